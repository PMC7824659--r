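#' Spatial relocation kernel
#'
#' A spatial kernel is a row-stochastic matrix \eqn{H} whose entry
#' \eqn{h_{ij}} is the probability that a mover leaving zone \eqn{i}
#' settles in zone \eqn{j}. It is the spatial term of the mover-stayer
#' decomposition \eqn{P = (1-\epsilon)I + \epsilon H}: the "migration
#' potential" of the urban area, independent of how often people move.
#'
#' Kernels estimated from flow tables have a structurally zero diagonal
#' (a move is, by definition, a change of zone). Kernels of synthetic toy
#' cities may carry positive diagonals; the \code{zero_diagonal} flag
#' records which convention a kernel follows.
#'
#' @param h numeric square matrix of nonnegative destination weights; rows
#'   are normalised to sum to one at construction when within \code{tol}
#'   of doing so, otherwise an error is raised.
#' @param zone_ids character vector of zone labels; defaults to existing
#'   dimnames or \code{z1..zN}.
#' @param zero_diagonal logical; if \code{TRUE}, the diagonal must be
#'   exactly zero.
#' @param tol row-sum tolerance accepted at construction (renormalisation
#'   happens here and only here).
#' @return an object of class \code{"spatial_kernel"}: the matrix with
#'   zone ids as dimnames and a \code{zero_diagonal} attribute.
#' @examples
#' H <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
#' rowSums(H)
#' @export
spatial_kernel <- function(h, zone_ids = NULL, zero_diagonal = FALSE,
                           tol = 1e-9) {
  h <- as.matrix(h)
  if (nrow(h) != ncol(h)) stop("kernel must be square")
  if (nrow(h) < 2L) stop("kernel needs at least 2 zones")
  if (any(!is.finite(h))) stop("kernel entries must be finite")
  if (any(h < 0)) stop("kernel entries must be nonnegative")
  zone_ids <- resolve_zone_ids(zone_ids, h)
  rs <- rowSums(h)
  if (any(abs(rs - 1) > tol)) {
    stop("kernel rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  h <- h / rs
  if (zero_diagonal) {
    if (any(diag(h) != 0)) stop("diagonal must be exactly zero")
  }
  dimnames(h) <- list(zone_ids, zone_ids)
  structure(h, zero_diagonal = zero_diagonal, class = "spatial_kernel")
}

#' @export
print.spatial_kernel <- function(x, ...) {
  cat("Spatial kernel:", nrow(x), "zones",
      if (isTRUE(attr(x, "zero_diagonal"))) "(zero diagonal)" else "",
      "\n")
  print(unclass_matrix(x), ...)
  invisible(x)
}

is_spatial_kernel <- function(x) inherits(x, "spatial_kernel")

# strip class/attrs for plain linear algebra
unclass_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "zero_diagonal") <- NULL
  m
}

resolve_zone_ids <- function(zone_ids, m) {
  n <- nrow(m)
  if (is.null(zone_ids)) {
    zone_ids <- rownames(m)
    if (is.null(zone_ids)) zone_ids <- paste0("z", seq_len(n))
  }
  zone_ids <- as.character(zone_ids)
  if (length(zone_ids) != n) stop("zone_ids length does not match matrix")
  if (anyDuplicated(zone_ids)) stop("duplicate zone ids")
  zone_ids
}

#' Estimate the destination-choice kernel from a flow table
#'
#' Off-diagonal relocation counts are normalised per origin:
#' \eqn{h_{ij} = T_{ij} / \sum_{k \ne i} T_{ik}} for \eqn{j \ne i} and
#' \eqn{h_{ii} = 0}. Diagonal counts (people who did not change zone) are
#' ignored: the kernel conditions on having moved.
#'
#' @param flows a [flow_matrix] (or plain square nonnegative matrix).
#' @param zero_rows policy for origins with no off-diagonal flow:
#'   \code{"error"} (default) or \code{"uniform"}, which assigns
#'   \eqn{1/(N-1)} to every other zone with a warning.
#' @return a [spatial_kernel] with a zero diagonal.
#' @examples
#' T1 <- flow_matrix(matrix(c(0, 10, 30, 0), 2, 2, byrow = TRUE))
#' kernel_from_flows(T1)
#' @export
kernel_from_flows <- function(flows, zero_rows = c("error", "uniform")) {
  zero_rows <- match.arg(zero_rows)
  m <- if (inherits(flows, "flow_matrix")) unclass_flow(flows) else as.matrix(flows)
  if (nrow(m) != ncol(m)) stop("flow matrix must be square")
  if (any(m < 0)) stop("flow counts must be nonnegative")
  n <- nrow(m)
  off <- m
  diag(off) <- 0
  rs <- rowSums(off)
  bad <- rs == 0
  if (any(bad)) {
    if (zero_rows == "error") {
      stop("origin(s) with no off-diagonal flow: ",
           paste(resolve_zone_ids(NULL, m)[bad], collapse = ", "),
           " (use zero_rows = \"uniform\" to impute)")
    }
    warning(sum(bad), " zero-outflow row(s) imputed with uniform ",
            "destination weights 1/(N-1)")
    off[bad, ] <- 1 / (n - 1)
    diag(off) <- 0
    rs <- rowSums(off)
  }
  spatial_kernel(off / rs, zone_ids = rownames(m), zero_diagonal = TRUE)
}

#' Aggregate the kernels of a mixture
#'
#' Returns the population-weighted kernel \eqn{\hat H = \sum_k \alpha_k H_k},
#' the only kernel observable when component memberships are unknown. A
#' convex combination of row-stochastic matrices, hence row-stochastic.
#'
#' @param mixture a [component_mixture].
#' @return a [spatial_kernel].
#' @export
aggregate_kernel <- function(mixture) {
  stopifnot(inherits(mixture, "component_mixture"))
  ks <- lapply(mixture$components, `[[`, "kernel")
  ids <- lapply(ks, rownames)
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("component kernels must share zone ids")
  }
  al <- vapply(mixture$components, `[[`, numeric(1), "alpha")
  hhat <- Reduce(`+`, Map(function(a, k) a * unclass_matrix(k), al, ks))
  zd <- all(vapply(ks, function(k) isTRUE(attr(k, "zero_diagonal")),
                   logical(1)))
  spatial_kernel(hhat, zone_ids = ids[[1]], zero_diagonal = zd)
}

#' Split a kernel into centre-seeking and periphery-seeking components
#'
#' Decomposes a row-stochastic kernel \eqn{H} into two row-stochastic
#' kernels with \eqn{\alpha H_1 + (1-\alpha) H_2 = H} exactly, where
#' \eqn{H_1} routes its movers into a designated destination set \eqn{A}
#' (e.g. zones within a distance threshold of the central business
#' district) as far as the observed flows allow, and \eqn{H_2} takes the
#' remainder. With \eqn{a_i = \sum_{j \in A} h_{ij}} the observed share of
#' row \eqn{i}'s movers heading into \eqn{A}:
#' \itemize{
#'   \item if \eqn{a_i \le \alpha}: \eqn{h_{1;ij} = h_{ij}/\alpha} for
#'     \eqn{j \in A} and \eqn{h_{1;ij} = h_{ij}(\alpha - a_i)/(\alpha(1-a_i))}
#'     otherwise;
#'   \item if \eqn{a_i > \alpha}: \eqn{h_{1;ij} = h_{ij}/a_i} for
#'     \eqn{j \in A} and zero otherwise;
#' }
#' and in both cases \eqn{h_{2;ij} = (h_{ij} - \alpha h_{1;ij})/(1-\alpha)}.
#'
#' @param H a [spatial_kernel].
#' @param set_A destination set: zone ids (character) or indices (numeric);
#'   must be a nonempty proper subset.
#' @param alpha share of component 1, in (0, 1).
#' @return list with elements \code{H1}, \code{H2} (spatial kernels),
#'   \code{a} (the per-row shares \eqn{a_i}) and \code{alpha}.
#' @export
split_kernel <- function(H, set_A, alpha) {
  stopifnot(is_spatial_kernel(H))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  n <- nrow(H)
  idx <- resolve_zone_subset(set_A, rownames(H))
  if (length(idx) == 0L || length(idx) == n) {
    stop("set_A must be a nonempty proper subset of the zones")
  }
  h <- unclass_matrix(H)
  inA <- seq_len(n) %in% idx
  a <- rowSums(h[, inA, drop = FALSE])
  h1 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (a[i] <= alpha) {
      if (1 - a[i] <= 0) stop("degenerate row ", i, ": a_i = 1 with a_i <= alpha")
      h1[i, inA] <- h[i, inA] / alpha
      h1[i, !inA] <- h[i, !inA] * (alpha - a[i]) / (alpha * (1 - a[i]))
    } else {
      h1[i, inA] <- h[i, inA] / a[i]
      # zero outside A
    }
  }
  h2 <- (h - alpha * h1) / (1 - alpha)
  # clip roundoff just below zero before validation
  h2[h2 < 0 & h2 > -1e-14] <- 0
  H1 <- spatial_kernel(h1, zone_ids = rownames(H))
  H2 <- spatial_kernel(h2, zone_ids = rownames(H))
  list(H1 = H1, H2 = H2, a = stats::setNames(a, rownames(H)), alpha = alpha)
}

resolve_zone_subset <- function(set_A, zone_ids) {
  if (is.character(set_A)) {
    idx <- match(set_A, zone_ids)
    if (anyNA(idx)) stop("unknown zone id(s): ",
                         paste(set_A[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(set_A)
    if (any(idx < 1L | idx > length(zone_ids))) stop("zone index out of range")
  }
  sort(unique(idx))
}
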