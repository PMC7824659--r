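#' Origin-destination flow matrix
#'
#' Square table of relocation counts \eqn{T_{ij}}: residents of zone
#' \eqn{i} at the start of the window living in zone \eqn{j} at its end.
#' The diagonal holds within-zone (non-moving) counts when the source
#' records them.
#'
#' @param counts square nonnegative numeric matrix.
#' @param window_years positive integer length of the observation window
#'   (census tables typically use 1 or 5).
#' @param zone_ids zone labels; defaults to dimnames or \code{z1..zN}.
#' @return an object of class \code{"flow_matrix"}.
#' @export
flow_matrix <- function(counts, window_years = 1L, zone_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("flow matrix must be square")
  if (any(!is.finite(counts))) stop("flow counts must be finite")
  if (any(counts < 0)) stop("flow counts must be nonnegative")
  window_years <- as.integer(window_years)
  if (is.na(window_years) || window_years < 1L) {
    stop("window_years must be a positive integer")
  }
  zone_ids <- resolve_zone_ids(zone_ids, counts)
  dimnames(counts) <- list(zone_ids, zone_ids)
  structure(counts, window_years = window_years, class = "flow_matrix")
}

unclass_flow <- function(x) {
  m <- unclass(x)
  attr(m, "window_years") <- NULL
  m
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat("Flow matrix:", nrow(x), "zones,", attr(x, "window_years"),
      "year window\n")
  print(unclass_flow(x), ...)
  invisible(x)
}

#' Per-zone population vector
#'
#' @param values nonnegative headcounts.
#' @param zone_ids zone labels; defaults to names or \code{z1..zN}.
#' @return a named numeric vector of class \code{"population_vector"};
#'   its sum is the fixed total \eqn{\bar x} of the closed system.
#' @export
population_vector <- function(values, zone_ids = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 zones")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("populations must be finite and nonnegative")
  }
  if (is.null(zone_ids)) zone_ids <- names(values)
  if (is.null(zone_ids)) zone_ids <- paste0("z", seq_along(values))
  zone_ids <- as.character(zone_ids)
  if (length(zone_ids) != length(values)) stop("zone_ids length mismatch")
  if (anyDuplicated(zone_ids)) stop("duplicate zone ids")
  structure(stats::setNames(values, zone_ids), class = "population_vector")
}

#' @export
print.population_vector <- function(x, ...) {
  cat("Population vector:", length(x), "zones, total",
      format(sum(x)), "\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

as_population <- function(x) {
  if (inherits(x, "population_vector")) x else population_vector(x)
}

#' Mover-stayer relocation matrix
#'
#' The one-step relocation matrix \eqn{P = (1-\epsilon) I + \epsilon H}:
#' with probability \eqn{\epsilon} a resident moves, choosing a
#' destination by the kernel row; otherwise they stay. \eqn{\epsilon} is
#' the relocation frequency per time step and \eqn{\tau = 1/\epsilon} the
#' characteristic relocation time.
#'
#' @param kernel a [spatial_kernel].
#' @param epsilon relocation frequency in \eqn{[0, 1]}.
#' @return row-stochastic numeric matrix with the kernel's zone ids.
#' @examples
#' H <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2))
#' mover_stayer_matrix(H, 0.1)
#' @export
mover_stayer_matrix <- function(kernel, epsilon) {
  stopifnot(is_spatial_kernel(kernel))
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single number in [0, 1]")
  }
  h <- unclass_matrix(kernel)
  p <- (1 - epsilon) * diag(nrow(h)) + epsilon * h
  dimnames(p) <- dimnames(h)
  p
}

#' Single-component relocation model
#'
#' Bundles a relocation frequency with a spatial kernel; the implied
#' one-step matrix is \code{mover_stayer_matrix(kernel, epsilon)}.
#'
#' @param epsilon relocation frequency in \eqn{[0, 1]}.
#' @param kernel a [spatial_kernel].
#' @return object of class \code{"relocation_model"} with fields
#'   \code{epsilon}, \code{kernel}, \code{tau} (\code{Inf} when
#'   \code{epsilon} is 0).
#' @export
relocation_model <- function(epsilon, kernel) {
  stopifnot(is_spatial_kernel(kernel))
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      is.na(epsilon) || epsilon < 0 || epsilon > 1) {
    stop("epsilon must be a single number in [0, 1]")
  }
  structure(list(epsilon = epsilon, kernel = kernel,
                 tau = if (epsilon > 0) 1 / epsilon else Inf),
            class = "relocation_model")
}

#' @export
print.relocation_model <- function(x, ...) {
  cat("Mover-stayer relocation model\n")
  cat("  zones:  ", nrow(x$kernel), "\n")
  cat("  epsilon:", format(x$epsilon),
      " (tau =", format(x$tau), "years)\n")
  invisible(x)
}

#' Multi-component relocation mixture
#'
#' Population split into \eqn{K} groups; group \eqn{k} holds share
#' \eqn{\alpha_k} of the population and follows its own mover-stayer
#' matrix \eqn{P_k = (1-\epsilon_k) I + \epsilon_k H_k}. Groups may share
#' a kernel (the homogeneous-space case) or not.
#'
#' @param alphas population shares, each in (0, 1], summing to 1 within
#'   1e-12.
#' @param epsilons relocation frequencies, one per component.
#' @param kernels a single [spatial_kernel] (shared by all components) or
#'   a list of kernels, one per component.
#' @return object of class \code{"component_mixture"}.
#' @export
component_mixture <- function(alphas, epsilons, kernels) {
  alphas <- as.numeric(alphas)
  epsilons <- as.numeric(epsilons)
  k <- length(alphas)
  if (k < 1L) stop("need at least one component")
  if (length(epsilons) != k) stop("alphas and epsilons lengths differ")
  if (any(alphas <= 0) || any(alphas > 1)) stop("alphas must be in (0, 1]")
  if (abs(sum(alphas) - 1) > 1e-12) stop("alphas must sum to 1")
  if (any(epsilons < 0) || any(epsilons > 1)) {
    stop("epsilons must be in [0, 1]")
  }
  if (is_spatial_kernel(kernels)) {
    kernels <- rep(list(kernels), k)
    shared <- TRUE
  } else {
    if (!is.list(kernels) || length(kernels) != k ||
        !all(vapply(kernels, is_spatial_kernel, logical(1)))) {
      stop("kernels must be one spatial_kernel or a list of length K")
    }
    shared <- k == 1L ||
      all(vapply(kernels[-1], function(kk) {
        isTRUE(all.equal(unclass_matrix(kk), unclass_matrix(kernels[[1]]),
                         tolerance = 1e-12))
      }, logical(1)))
  }
  ids <- lapply(kernels, rownames)
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("component kernels must share zone ids")
  }
  comps <- Map(function(a, e, kk) list(alpha = a, epsilon = e, kernel = kk),
               alphas, epsilons, kernels)
  structure(list(components = comps, shared_kernel = shared),
            class = "component_mixture")
}

#' @export
print.component_mixture <- function(x, ...) {
  k <- length(x$components)
  cat("Relocation mixture:", k, "component(s),",
      if (x$shared_kernel) "shared kernel" else "component-specific kernels",
      "\n")
  for (i in seq_len(k)) {
    c_i <- x$components[[i]]
    cat(sprintf("  [%d] alpha = %-8s epsilon = %s\n", i,
                format(c_i$alpha), format(c_i$epsilon)))
  }
  invisible(x)
}

n_zones <- function(model) {
  if (inherits(model, "relocation_model")) nrow(model$kernel)
  else if (inherits(model, "component_mixture")) {
    nrow(model$components[[1]]$kernel)
  } else if (is_spatial_kernel(model)) nrow(model)
  else stop("not a relocation model, mixture or kernel")
}

model_zone_ids <- function(model) {
  if (inherits(model, "relocation_model")) rownames(model$kernel)
  else if (inherits(model, "component_mixture")) {
    rownames(model$components[[1]]$kernel)
  } else if (is_spatial_kernel(model)) rownames(model)
  else stop("not a relocation model, mixture or kernel")
}

component_matrices <- function(model) {
  if (inherits(model, "relocation_model")) {
    list(mover_stayer_matrix(model$kernel, model$epsilon))
  } else if (inherits(model, "component_mixture")) {
    lapply(model$components,
           function(c_k) mover_stayer_matrix(c_k$kernel, c_k$epsilon))
  } else stop("not a relocation model or mixture")
}

component_alphas <- function(model) {
  if (inherits(model, "relocation_model")) 1
  else vapply(model$components, `[[`, numeric(1), "alpha")
}

#' Naive one-window relocation rates
#'
#' Direct rate estimate \eqn{p_{ij} = T_{ij} / x_i}, dividing each
#' origin's flow row (diagonal included) by its population. When the flow
#' table accounts for everyone (row sums equal \eqn{x_i}) the result is
#' row-stochastic.
#'
#' @param flows a [flow_matrix] whose diagonal carries the stayers.
#' @param population a [population_vector] aligned with the flows.
#' @return row-stochastic numeric matrix.
#' @export
naive_rates <- function(flows, population) {
  stopifnot(inherits(flows, "flow_matrix"))
  x <- as_population(population)
  m <- unclass_flow(flows)
  if (length(x) != nrow(m)) stop("population length does not match flows")
  if (!is.null(names(x)) && !identical(names(x), rownames(m))) {
    stop("zone ids of population and flows disagree")
  }
  if (any(x <= 0)) stop("every zone needs positive population")
  rs <- rowSums(m)
  if (any(rs > as.numeric(x) * (1 + 1e-12))) {
    stop("row flow total exceeds origin population")
  }
  p <- m / as.numeric(x)
  dimnames(p) <- dimnames(m)
  p
}

#' Transport matrix of the relaxation dynamics
#'
#' The discrete transport operator \eqn{L = P - I = -\epsilon(I - H)}
#' mapping the driving force \eqn{U(t) = X(t) - X_{eq}} to the rate of
#' change \eqn{Q(t) = X(t+1) - X(t)} via \eqn{Q = U L}. Rows sum to zero.
#'
#' @param model a [relocation_model].
#' @return numeric matrix with zero row sums.
#' @export
transport_matrix <- function(model) {
  stopifnot(inherits(model, "relocation_model"))
  h <- unclass_matrix(model$kernel)
  l <- -model$epsilon * (diag(nrow(h)) - h)
  dimnames(l) <- dimnames(h)
  l
}
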