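mat_pow <- function(p, t) {
  # repeated multiplication, not eigendecomposition: horizons are small
  # (censal windows, <= a few decades) and this keeps results bit-stable
  out <- diag(nrow(p))
  dimnames(out) <- dimnames(p)
  for (i in seq_len(t)) out <- out %*% p
  out
}

#' Evolve a population under a relocation model
#'
#' Iterates the evolution equation \eqn{X(t+1) = X(t) P} (row-vector
#' convention) for a single-component model, or each component
#' independently under its own \eqn{P_k} for a mixture. The total
#' population is conserved at every step: the system is closed.
#'
#' @param state initial [population_vector] \eqn{X(0)}.
#' @param model a [relocation_model] or [component_mixture].
#' @param steps number of one-year steps, \eqn{\ge 0}.
#' @param component_states optional list of per-component initial vectors
#'   (mixtures only); defaults to the proportional split
#'   \eqn{\alpha_k X(0)}.
#' @return object of class \code{"relaxation_trace"}: a list with
#'   \code{times} (0..steps), \code{states} (matrix, one row per step),
#'   \code{rates} \eqn{Q(t) = X(t+1)-X(t)}, \code{driving_forces}
#'   \eqn{U(t) = X(t)-X_{eq}}, per-component analogues, and the
#'   [equilibrium] used for \eqn{U}.
#' @examples
#' H <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2))
#' m <- relocation_model(0.1, H)
#' tr <- evolve(population_vector(c(100, 0)), m, 10)
#' tr$states[11, ]  # near (50, 50)
#' @export
evolve <- function(state, model, steps, component_states = NULL) {
  x0 <- as_population(state)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) stop("steps must be >= 0")
  n <- n_zones(model)
  if (length(x0) != n) stop("state length does not match model zones")
  ids <- model_zone_ids(model)
  if (!is.null(names(x0)) && !identical(names(x0), ids) &&
      !all(names(x0) == paste0("z", seq_len(n)))) {
    stop("zone ids of state and model disagree")
  }
  ps <- component_matrices(model)
  al <- component_alphas(model)
  k <- length(ps)
  if (is.null(component_states)) {
    comp0 <- lapply(al, function(a) a * as.numeric(x0))
  } else {
    if (!is.list(component_states) || length(component_states) != k) {
      stop("component_states must be a list with one vector per component")
    }
    comp0 <- lapply(component_states, as.numeric)
    if (any(vapply(comp0, length, integer(1)) != n)) {
      stop("component state length mismatch")
    }
    tot <- Reduce(`+`, comp0)
    if (max(abs(tot - as.numeric(x0))) > 1e-6 * sum(x0)) {
      stop("component states must sum to the total state")
    }
  }
  eq <- if (inherits(model, "component_mixture")) {
    mixture_equilibrium(model, total = sum(x0))
  } else {
    stationary_distribution(model, total = sum(x0))
  }
  comp_tr <- vector("list", k)
  for (j in seq_len(k)) {
    st <- matrix(NA_real_, steps + 1L, n, dimnames = list(NULL, ids))
    v <- comp0[[j]]
    st[1L, ] <- v
    for (t in seq_len(steps)) {
      v <- as.numeric(v %*% ps[[j]])
      st[t + 1L, ] <- v
    }
    comp_tr[[j]] <- st
  }
  states <- Reduce(`+`, comp_tr)
  rates <- if (steps > 0L) {
    states[-1L, , drop = FALSE] - states[-(steps + 1L), , drop = FALSE]
  } else {
    matrix(numeric(0), 0L, n, dimnames = list(NULL, ids))
  }
  xeq <- as.numeric(eq$x_eq)
  drv <- sweep(states, 2L, xeq)
  comp_drv <- Map(function(st, xk) sweep(st, 2L, as.numeric(xk)),
                  comp_tr, eq$per_component)
  comp_rates <- lapply(comp_tr, function(st) {
    if (steps > 0L) st[-1L, , drop = FALSE] - st[-(steps + 1L), , drop = FALSE]
    else matrix(numeric(0), 0L, n)
  })
  structure(list(times = 0:steps, states = states, rates = rates,
                 driving_forces = drv, component_states = comp_tr,
                 component_driving = comp_drv,
                 component_rates = comp_rates,
                 equilibrium = eq, x_bar = sum(x0)),
            class = "relaxation_trace")
}

#' @export
print.relaxation_trace <- function(x, ...) {
  ns <- length(x$times) - 1L
  cat("Relaxation trace:", ns, "steps,", ncol(x$states), "zones, total",
      format(x$x_bar), "\n")
  un <- sqrt(sum(x$driving_forces[nrow(x$driving_forces), ]^2))
  cat("  terminal ||U|| =", format(un), "\n")
  invisible(x)
}

#' @export
plot.relaxation_trace <- function(x, log = "y", ...) {
  un <- apply(x$driving_forces, 1L, function(u) sqrt(sum(u^2)))
  keep <- un > 0
  graphics::plot(x$times[keep], un[keep], log = log, type = "b",
                 xlab = "t (years)", ylab = "||U(t)||", ...)
  invisible(x)
}

#' Net inter-zone flow
#'
#' Antisymmetric matrix \eqn{J_{ij} = x_i p_{ij} - x_j p_{ji}}; nonzero
#' net flow marks a system out of equilibrium.
#'
#' @param state a [population_vector].
#' @param model a [relocation_model].
#' @return antisymmetric numeric matrix (\eqn{J = -J^T} exactly).
#' @export
net_flow <- function(state, model) {
  stopifnot(inherits(model, "relocation_model"))
  x <- as.numeric(as_population(state))
  if (length(x) != n_zones(model)) stop("dimension mismatch")
  p <- mover_stayer_matrix(model$kernel, model$epsilon)
  tij <- x * p   # row i scaled by x_i
  j <- tij - t(tij)
  dimnames(j) <- dimnames(p)
  j
}

#' Extrapolate relocation flows over a horizon
#'
#' Predicted window flows \eqn{\hat T_{ij} = x_i [\sum_k \alpha_k
#' P_k^{t}]_{ij}} for horizon \eqn{t} years: each component's matrix is
#' raised to the horizon by repeated multiplication, then mixed. With one
#' component this is the naive extrapolation \eqn{x_i [P^t]_{ij}} whose
#' five-year stayer counts systematically undershoot observed ones when
#' the population is heterogeneous in mobility.
#'
#' @param population [population_vector] at the window start.
#' @param model a [relocation_model] or [component_mixture].
#' @param horizon_years integer \eqn{\ge 1}.
#' @return a [flow_matrix] with \code{window_years = horizon_years}.
#' @export
extrapolate_flows <- function(population, model, horizon_years) {
  x <- as_population(population)
  horizon_years <- as.integer(horizon_years)
  if (is.na(horizon_years) || horizon_years < 1L) stop("horizon must be >= 1")
  if (length(x) != n_zones(model)) stop("dimension mismatch")
  ps <- component_matrices(model)
  al <- component_alphas(model)
  mixp <- Reduce(`+`, Map(function(a, p) a * mat_pow(p, horizon_years),
                          al, ps))
  counts <- as.numeric(x) * mixp
  flow_matrix(counts, window_years = horizon_years,
              zone_ids = model_zone_ids(model))
}

#' Stayer share over a horizon
#'
#' The share of residents whose zone after \code{horizon_years} steps
#' equals their starting zone, under the model: the weighted mean of
#' \eqn{\mathrm{diag}(\sum_k \alpha_k P_k^{t})}. With population weights
#' (the default when supplied) zones contribute in proportion to their
#' headcount; otherwise the plain mean over zones is used.
#'
#' @param model a [relocation_model] or [component_mixture].
#' @param horizon_years integer \eqn{\ge 0}; 0 returns 1.
#' @param weights optional [population_vector] of zone weights; omitted
#'   means unweighted.
#' @return a share in \eqn{[0, 1]}.
#' @export
stayer_share <- function(model, horizon_years, weights = NULL) {
  horizon_years <- as.integer(horizon_years)
  if (is.na(horizon_years) || horizon_years < 0L) stop("horizon must be >= 0")
  if (horizon_years == 0L) return(1)
  ps <- component_matrices(model)
  al <- component_alphas(model)
  d <- Reduce(`+`, Map(function(a, p) a * diag(mat_pow(p, horizon_years)),
                       al, ps))
  if (is.null(weights)) {
    mean(d)
  } else {
    w <- as.numeric(as_population(weights))
    if (length(w) != length(d)) stop("weights length mismatch")
    sum(w * d) / sum(w)
  }
}
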