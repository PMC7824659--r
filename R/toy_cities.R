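#' Linear toy-city kernels
#'
#' A one-dimensional city of \code{n_zones} suburbs on a line with a
#' central suburb at \code{center}; \eqn{d_j = |j - center|} is the
#' distance of suburb \eqn{j} from the centre. Two opposed destination
#' kernels are produced: the centre-seeking \eqn{h_{1;ij} \propto
#' e^{-\beta d_j}} and the periphery-seeking \eqn{h_{2;ij} \propto
#' e^{+\beta d_j}}, each row normalised over destinations. Origin
#' distance cancels in the normalisation, so all rows of either kernel
#' are identical and equal its stationary distribution: unimodal at the
#' centre for \eqn{H_1}, maximal at the two boundary zones for
#' \eqn{H_2}. Diagonals are not forced to zero (a "move" may end in the
#' same zone), unlike kernels estimated from flow tables.
#'
#' @param n_zones number of suburbs (default 99).
#' @param beta distance-decay rate per zone (default 0.1).
#' @param center index of the central suburb, 1-based (default 50).
#' @return list with spatial kernels \code{H1} (centre-seeking) and
#'   \code{H2} (periphery-seeking) and the distance vector \code{d}.
#' @examples
#' lc <- linear_city_kernels(n_zones = 9, beta = 0.5, center = 5)
#' stationary_distribution(lc$H1)$x_eq
#' @export
linear_city_kernels <- function(n_zones = 99L, beta = 0.1, center = 50L) {
  n_zones <- as.integer(n_zones)
  if (is.na(n_zones) || n_zones < 3L) stop("need at least 3 zones")
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > n_zones) {
    stop("center out of range")
  }
  if (beta < 0) stop("beta must be >= 0")
  d <- abs(seq_len(n_zones) - center)
  ids <- paste0("z", seq_len(n_zones))
  row1 <- exp(-beta * d)
  row2 <- exp(beta * d)
  h1 <- matrix(row1 / sum(row1), n_zones, n_zones, byrow = TRUE)
  h2 <- matrix(row2 / sum(row2), n_zones, n_zones, byrow = TRUE)
  list(H1 = spatial_kernel(h1, zone_ids = ids),
       H2 = spatial_kernel(h2, zone_ids = ids),
       d = d)
}

#' Random block toy-city kernels
#'
#' Kernels with disjoint destination supports: \eqn{H_1} has positive
#' (uniform random) entries exactly in the columns of \code{set_A} and
#' zeros elsewhere, \eqn{H_2} the complement; every row is normalised to
#' sum to one. All movers of component 1 end up inside \code{set_A}, so
#' the stationary vector of \eqn{H_1} is supported within \code{set_A}
#' (and symmetrically for \eqn{H_2}). Matrices are deterministic given
#' \code{seed}; the caller's RNG state is left untouched.
#'
#' @param n_zones number of suburbs.
#' @param set_A destination zone indices (or ids) for component 1;
#'   nonempty proper subset.
#' @param seed integer seed for the random entries.
#' @return list with spatial kernels \code{H1}, \code{H2} and the
#'   resolved index set \code{set_A}.
#' @export
random_block_kernels <- function(n_zones = 99L, set_A = 26:74, seed = 1L) {
  n_zones <- as.integer(n_zones)
  if (is.na(n_zones) || n_zones < 2L) stop("need at least 2 zones")
  ids <- paste0("z", seq_len(n_zones))
  idx <- resolve_zone_subset(set_A, ids)
  if (length(idx) == 0L || length(idx) == n_zones) {
    stop("set_A must be a nonempty proper subset")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  inA <- seq_len(n_zones) %in% idx
  h1 <- matrix(0, n_zones, n_zones)
  h2 <- matrix(0, n_zones, n_zones)
  h1[, inA] <- stats::runif(n_zones * sum(inA))
  h2[, !inA] <- stats::runif(n_zones * sum(!inA))
  h1 <- h1 / rowSums(h1)
  h2 <- h2 / rowSums(h2)
  list(H1 = spatial_kernel(h1, zone_ids = ids),
       H2 = spatial_kernel(h2, zone_ids = ids),
       set_A = idx)
}

#' Ready-made relocation mixtures for the toy cities
#'
#' Convenience constructor bundling the toy-city generators with
#' component shares and relocation frequencies into a
#' [component_mixture]:
#' \describe{
#'   \item{\code{"shared"}}{both components use the centre-seeking
#'     linear-city kernel (homogeneous space, heterogeneous mobility).}
#'   \item{\code{"opposed"}}{component 1 centre-seeking, component 2
#'     periphery-seeking, from [linear_city_kernels()].}
#'   \item{\code{"blocks"}}{disjoint destination supports from
#'     [random_block_kernels()].}
#'   \item{\code{"split"}}{a supplied kernel decomposed by
#'     [split_kernel()] at \code{alphas[1]} over \code{set_A}.}
#' }
#'
#' @param kind one of \code{"shared"}, \code{"opposed"},
#'   \code{"blocks"}, \code{"split"}.
#' @param alphas component shares (length 2, sum 1).
#' @param epsilons component relocation frequencies (length 2).
#' @param n_zones,beta,center linear-city parameters.
#' @param set_A destination set for \code{"blocks"}/\code{"split"}.
#' @param seed RNG seed for \code{"blocks"}.
#' @param kernel base [spatial_kernel] for \code{"split"}.
#' @return a [component_mixture].
#' @export
mixture_fixture <- function(kind = c("shared", "opposed", "blocks", "split"),
                            alphas = c(0.5, 0.5), epsilons = c(0.1, 0.2),
                            n_zones = 99L, beta = 0.1, center = 50L,
                            set_A = 26:74, seed = 1L, kernel = NULL) {
  kind <- match.arg(kind)
  kernels <- switch(kind,
    shared = linear_city_kernels(n_zones, beta, center)$H1,
    opposed = {
      lc <- linear_city_kernels(n_zones, beta, center)
      list(lc$H1, lc$H2)
    },
    blocks = {
      bk <- random_block_kernels(n_zones, set_A, seed)
      list(bk$H1, bk$H2)
    },
    split = {
      if (is.null(kernel)) stop("kind = \"split\" needs a base kernel")
      sp <- split_kernel(kernel, set_A, alphas[1])
      list(sp$H1, sp$H2)
    })
  component_mixture(alphas, epsilons, kernels)
}
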