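#' Stationary population distribution
#'
#' The equilibrium city: the left eigenvector of the relocation matrix
#' for eigenvalue 1, scaled to the total population \eqn{\bar x}. Because
#' \eqn{P = (1-\epsilon)I + \epsilon H} shares left eigenvectors with
#' \eqn{H}, the equilibrium is the same for every \eqn{\epsilon \in
#' (0, 1]}: it depends on the spatial kernel only, not on how often
#' people move.
#'
#' Uniqueness holds when some power of the matrix is strictly positive
#' (primitivity). When the check fails (e.g. absorbing destination sets)
#' the result is flagged, not rejected: \code{is_unique = FALSE} and the
#' vector reported is the power-iteration limit from a uniform start, one
#' member of the dominant eigenspace.
#'
#' @param model a [relocation_model], [spatial_kernel], or plain
#'   row-stochastic matrix.
#' @param total total population \eqn{\bar x} the vector is scaled to.
#' @param tol acceptance tolerance for the unit-eigenvalue residual.
#' @return object of class \code{"equilibrium"}: \code{x_eq}
#'   ([population_vector]), \code{per_component} (list; a single entry
#'   here), \code{second_eigenvalue_modulus}, \code{is_unique},
#'   \code{total}.
#' @examples
#' H <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2))
#' stationary_distribution(H, total = 100)$x_eq
#' @export
stationary_distribution <- function(model, total = 1, tol = 1e-8) {
  p <- if (inherits(model, "relocation_model")) {
    mover_stayer_matrix(model$kernel, model$epsilon)
  } else if (is_spatial_kernel(model)) {
    unclass_matrix(model)
  } else {
    as.matrix(model)
  }
  if (nrow(p) != ncol(p)) stop("matrix must be square")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("matrix must be row-stochastic")
  }
  ids <- resolve_zone_ids(NULL, p)
  uniq <- is_primitive(p)
  ev <- eigen(t(p))
  mods <- Mod(ev$values)
  ord <- order(mods, decreasing = TRUE)
  lambda2 <- if (length(mods) > 1L) mods[ord][2L] else 0
  if (uniq) {
    i1 <- which.min(Mod(ev$values - 1))
    v <- Re(ev$vectors[, i1])
    if (sum(v) < 0) v <- -v
    v[v < 0 & v > -1e-12] <- 0
    if (any(v < 0)) v <- power_iterate(p)   # eigen sign pathology fallback
  } else {
    v <- power_iterate(p)
  }
  v <- v / sum(v)
  res <- max(abs(as.numeric(v %*% p) - v))
  if (res > tol) stop("stationary residual ", format(res), " exceeds tol")
  x_eq <- population_vector(total * v, zone_ids = ids)
  structure(list(x_eq = x_eq, per_component = list(x_eq),
                 second_eigenvalue_modulus = lambda2,
                 is_unique = uniq, total = total),
            class = "equilibrium")
}

power_iterate <- function(p, max_iter = 10000L, tol = 1e-14) {
  # damped iteration on (P + I)/2: same left eigenvectors for eigenvalue
  # 1 as P, but aperiodic, so it also converges for periodic chains
  v <- rep(1 / nrow(p), nrow(p))
  for (i in seq_len(max_iter)) {
    v2 <- (as.numeric(v %*% p) + v) / 2
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# primitivity: some power m <= N of the support pattern is all-positive
is_primitive <- function(p, eps = 1e-15) {
  a <- (p > eps) * 1
  ak <- a
  n <- nrow(p)
  if (all(ak > 0)) return(TRUE)
  for (m in seq_len(n - 1L)) {
    ak <- (ak %*% a > 0) * 1
    if (all(ak > 0)) return(TRUE)
  }
  FALSE
}

#' @export
print.equilibrium <- function(x, ...) {
  cat("Equilibrium population (total", format(x$total), ")\n")
  cat("  unique:", x$is_unique,
      " |lambda2| =", format(x$second_eigenvalue_modulus), "\n")
  print(stats::setNames(as.numeric(x$x_eq), names(x$x_eq)), ...)
  invisible(x)
}

#' Equilibrium of a relocation mixture
#'
#' With a shared kernel every component relaxes to the same spatial
#' profile: \eqn{X_{k,eq} = \alpha_k X_{eq}} where \eqn{X_{eq}} is the
#' stationary vector of \eqn{H}, independent of the \eqn{\epsilon_k} and
#' \eqn{\alpha_k}. With component-specific kernels each component settles
#' on the stationary vector of its own \eqn{H_k} and the city equilibrium
#' is their \eqn{\alpha_k}-weighted sum.
#'
#' @param mixture a [component_mixture].
#' @param total total population \eqn{\bar x}.
#' @return an object of class \code{"equilibrium"} whose
#'   \code{per_component} list holds each \eqn{X_{k,eq}};
#'   \code{second_eigenvalue_modulus} is the largest \eqn{|\lambda_2|}
#'   across component kernels (the slowest spatial mode).
#' @export
mixture_equilibrium <- function(mixture, total = 1) {
  stopifnot(inherits(mixture, "component_mixture"))
  al <- component_alphas(mixture)
  if (any(al <= 0)) stop("alphas must be positive")
  ids <- model_zone_ids(mixture)
  if (mixture$shared_kernel) {
    base <- stationary_distribution(mixture$components[[1]]$kernel,
                                    total = total)
    per <- lapply(al, function(a) {
      population_vector(a * as.numeric(base$x_eq), zone_ids = ids)
    })
    out <- base
    out$per_component <- per
    return(out)
  }
  eqs <- lapply(mixture$components, function(c_k) {
    stationary_distribution(c_k$kernel, total = 1)
  })
  per <- Map(function(a, e) {
    population_vector(a * total * as.numeric(e$x_eq), zone_ids = ids)
  }, al, eqs)
  x_eq <- population_vector(Reduce(`+`, lapply(per, as.numeric)),
                            zone_ids = ids)
  structure(list(x_eq = x_eq, per_component = per,
                 second_eigenvalue_modulus =
                   max(vapply(eqs, `[[`, numeric(1),
                              "second_eigenvalue_modulus")),
                 is_unique = all(vapply(eqs, `[[`, logical(1), "is_unique")),
                 total = total),
            class = "equilibrium")
}

#' Error of the aggregate-kernel equilibrium approximation
#'
#' When component kernels differ, the true equilibrium \eqn{X_{eq} =
#' \sum_k X_{k,eq}} cannot be recovered from the aggregated kernel
#' \eqn{\hat H = \sum_k \alpha_k H_k} alone; the stationary vector
#' \eqn{\hat X_{eq}} of \eqn{\hat H} is only an approximation. This
#' returns the relative discrepancy \eqn{\|X_{eq} - \hat X_{eq}\| /
#' \bar x} (L1 by default), which is observed to stay small even for
#' drastically opposed component kernels.
#'
#' @param mixture a [component_mixture].
#' @param total total population.
#' @param norm \code{"l1"} (default) or \code{"l2"}.
#' @return scalar discrepancy with attributes \code{norm},
#'   \code{x_eq}, and \code{x_eq_hat}.
#' @export
equilibrium_approximation_error <- function(mixture, total = 1,
                                            norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  truth <- mixture_equilibrium(mixture, total = total)
  hat <- stationary_distribution(aggregate_kernel(mixture), total = total)
  d <- as.numeric(truth$x_eq) - as.numeric(hat$x_eq)
  err <- switch(norm, l1 = sum(abs(d)), l2 = sqrt(sum(d^2))) / total
  structure(err, norm = norm, x_eq = truth$x_eq, x_eq_hat = hat$x_eq)
}

#' Spectral relaxation diagnostics
#'
#' Near equilibrium the driving force decays exponentially at the rate of
#' the second-largest-modulus eigenvalue: \eqn{\|U(t)\| \sim
#' |\lambda_2(P)|^t}, so \eqn{\log\|U(t)\|} is asymptotically linear with
#' slope \eqn{\log|\lambda_2(P)|}, and the rate obeys the transport law
#' \eqn{\|Q(t)\| \sim (1-\lambda_2)\|U(t)\|}. This fits the tail slope of
#' \eqn{\log\|U(t)\|} and compares it with the spectral prediction. Note
#' \eqn{\lambda_2(P_k) = 1 - \epsilon_k(1 - \lambda_2(H))}: the kernel
#' sets the spatial mode, the relocation frequency its speed.
#'
#' @param trace a [relaxation_trace] from [evolve()], length \eqn{\ge 5}.
#' @param model the [relocation_model] that generated the trace, or the
#'   [component_mixture] together with \code{component}.
#' @param component component index for mixtures; its \eqn{U_k}, \eqn{Q_k}
#'   and \eqn{P_k} are analysed (per-component dynamics are Markov, the
#'   summed trace is not).
#' @param norm \code{"l2"} (default) or \code{"l1"}.
#' @param window integer vector of times for the tail fit; default the
#'   last half of the trace.
#' @param normalise divide norms by the component total \eqn{\alpha_k
#'   \bar x} before fitting (display convention; slopes are unaffected).
#' @return object of class \code{"decay_estimate"}: \code{fitted_slope},
#'   \code{predicted_slope} (\eqn{\log|\lambda_2(P)|}),
#'   \code{near_equilibrium_ratio} (terminal \eqn{\|Q\|/\|U\|}),
#'   \code{lambda2}, \code{norm_kind}, \code{window}.
#' @export
relaxation_diagnostics <- function(trace, model, component = NULL,
                                   norm = c("l2", "l1"), window = NULL,
                                   normalise = TRUE) {
  stopifnot(inherits(trace, "relaxation_trace"))
  norm <- match.arg(norm)
  nt <- length(trace$times)
  if (nt < 5L) stop("trace must have at least 5 time points")
  if (inherits(model, "component_mixture")) {
    if (is.null(component)) {
      if (length(model$components) > 1L) {
        stop("give a component index for a multi-component mixture")
      }
      component <- 1L
    }
    c_k <- model$components[[component]]
    p <- mover_stayer_matrix(c_k$kernel, c_k$epsilon)
    u <- trace$component_driving[[component]]
    q <- trace$component_rates[[component]]
    scale_tot <- c_k$alpha * trace$x_bar
  } else {
    stopifnot(inherits(model, "relocation_model"))
    p <- mover_stayer_matrix(model$kernel, model$epsilon)
    u <- trace$driving_forces
    q <- trace$rates
    scale_tot <- trace$x_bar
  }
  if (!is_primitive(p)) stop("model is not primitive; decay rate undefined")
  vnorm <- switch(norm, l2 = function(v) sqrt(sum(v^2)),
                  l1 = function(v) sum(abs(v)))
  un <- apply(u, 1L, vnorm)
  qn <- apply(q, 1L, vnorm)
  if (normalise) {
    un <- un / scale_tot
    qn <- qn / scale_tot
  }
  if (is.null(window)) {
    window <- trace$times[trace$times >= floor(max(trace$times) / 2)]
  }
  wi <- match(window, trace$times)
  if (anyNA(wi)) stop("window times outside the trace")
  if (all(un[wi] < 1e-12)) stop("already at equilibrium over the window")
  keep <- wi[un[wi] > 0]
  if (length(keep) < 2L) stop("too few nonzero points in the window")
  fit <- stats::lm(log(un[keep]) ~ trace$times[keep])
  fitted_slope <- unname(stats::coef(fit)[2L])
  lam <- eigen(p, only.values = TRUE)$values
  lam2 <- sort(Mod(lam), decreasing = TRUE)[2L]
  tq <- length(qn)
  ratio <- if (tq >= 1L && un[tq] > 0) qn[tq] / un[tq] else NA_real_
  structure(list(fitted_slope = fitted_slope,
                 predicted_slope = log(lam2),
                 near_equilibrium_ratio = ratio,
                 lambda2 = lam2, norm_kind = norm,
                 window = window),
            class = "decay_estimate")
}

#' @export
print.decay_estimate <- function(x, ...) {
  cat("Relaxation decay estimate (", x$norm_kind, " norm)\n", sep = "")
  cat("  fitted slope    :", format(x$fitted_slope), "\n")
  cat("  spectral slope  :", format(x$predicted_slope),
      " (|lambda2| =", format(x$lambda2), ")\n")
  cat("  terminal ||Q||/||U|| :", format(x$near_equilibrium_ratio), "\n")
  invisible(x)
}
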