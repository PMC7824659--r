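#' Calibrate a two-component mover-stayer model from stayer shares
#'
#' A homogeneous population with one-year stayer share \eqn{s_{1Y}}
#' predicts a five-year share \eqn{s_{1Y}^5}, which systematically
#' undershoots census observations. Splitting the population into two
#' groups with shares \eqn{\alpha, 1-\alpha} and relocation frequencies
#' \eqn{\epsilon_1, \epsilon_2} resolves the bias. The frequencies solve
#' \deqn{\alpha(1-\epsilon_1) + (1-\alpha)(1-\epsilon_2) = s_{1Y}}
#' \deqn{\alpha(1-\epsilon_1)^5 + (1-\alpha)(1-\epsilon_2)^5 = s_{5Y}}
#' with both frequencies in \eqn{[0, 1]}. The group share \eqn{\alpha}
#' cannot be identified from two window lengths and is a fixed input.
#'
#' The system is reduced to one unknown: with \eqn{a = 1-\epsilon_1},
#' the linear equation gives \eqn{b(a) = (s_{1Y} - \alpha a)/(1-\alpha)}
#' and the quintic residual \eqn{f(a) = \alpha a^5 + (1-\alpha) b(a)^5 -
#' s_{5Y}} is scanned densely over the feasible interval for sign
#' changes, each refined by bisection. Depending on \eqn{(s_{1Y}, s_{5Y},
#' \alpha)} there are zero, one, or two admissible roots; an empty root
#' set is a valid (flagged) outcome, not an error. Solutions exist
#' whenever \eqn{s_{1Y}^5 \le s_{5Y} \le s_{1Y}}.
#'
#' @param s1 one-year stayer share \eqn{s_{1Y}}, in (0, 1].
#' @param s5 five-year stayer share \eqn{s_{5Y}}; must satisfy
#'   \eqn{0 \le s_{5Y} \le s_{1Y}}.
#' @param alpha population share of component 1, in (0, 1). Default 0.9.
#' @param n_scan grid points of the dense sign scan.
#' @param tol bisection tolerance on \eqn{a}.
#' @return object of class \code{"mover_stayer_fit"} with fields
#'   \code{epsilon1}, \code{epsilon2} (the primary root; component 1 is
#'   the slow group when such a root exists), \code{alpha}, \code{s1},
#'   \code{s5}, \code{residuals} (both equation residuals),
#'   \code{n_solutions}, and \code{all_roots} (matrix; each row one
#'   admissible \eqn{(\epsilon_1, \epsilon_2)} pair, \eqn{\epsilon_1}
#'   tied to the \eqn{\alpha} share). Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict} (stayer curve),
#'   \code{plot}.
#' @examples
#' fit <- mover_stayer_fit(s1 = 0.91, s5 = 0.73, alpha = 0.95)
#' coef(fit)
#' predict(fit, horizons = c(1, 5, 30))
#' @export
mover_stayer_fit <- function(s1, s5, alpha = 0.9, n_scan = 10000L,
                             tol = 1e-12) {
  if (!(s1 > 0 && s1 <= 1)) stop("s1 must be in (0, 1]")
  if (s5 < 0 || s5 > s1) {
    stop("no solution: shares outside admissible region (need 0 <= s5 <= s1)")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  b_of <- function(a) (s1 - alpha * a) / (1 - alpha)
  f <- function(a) alpha * a^5 + (1 - alpha) * b_of(a)^5 - s5
  lo <- max(0, (s1 - (1 - alpha)) / alpha)
  hi <- min(1, s1 / alpha)
  grid <- seq(lo, hi, length.out = n_scan)
  fg <- f(grid)
  roots_a <- numeric(0)
  # exact hits on the grid
  zero_hit <- which(fg == 0)
  roots_a <- c(roots_a, grid[zero_hit])
  flips <- which(fg[-1] * fg[-n_scan] < 0)
  for (i in flips) {
    l <- grid[i]; u <- grid[i + 1L]
    fl <- fg[i]
    while (u - l > tol) {
      m <- (l + u) / 2
      fm <- f(m)
      if (fm == 0) { l <- m; u <- m; break }
      if (sign(fm) == sign(fl)) { l <- m; fl <- fm } else u <- m
    }
    roots_a <- c(roots_a, (l + u) / 2)
  }
  # tangent (double) roots touch zero at an interior extremum without a
  # sign change -- the boundary of the two-solution region, and the exact
  # s5 = s1^5 equal-frequency case; refine candidate extrema and keep
  # those where f itself vanishes
  interior <- 2:(n_scan - 1L)
  is_min <- fg[interior] <= fg[interior - 1L] & fg[interior] <= fg[interior + 1L]
  is_max <- fg[interior] >= fg[interior - 1L] & fg[interior] >= fg[interior + 1L]
  cand <- interior[(is_min & fg[interior] > 0 & fg[interior] < 1e-6) |
                   (is_max & fg[interior] < 0 & fg[interior] > -1e-6)]
  for (i in cand) {
    obj <- if (fg[i] > 0) f else function(a) -f(a)
    op <- stats::optimize(obj, c(grid[i - 1L], grid[i + 1L]), tol = 1e-12)
    if (abs(f(op$minimum)) < 1e-10) roots_a <- c(roots_a, op$minimum)
  }
  roots_a <- sort(unique(roots_a))
  if (length(roots_a) > 1L) {
    roots_a <- roots_a[c(TRUE, diff(roots_a) > 1e-9)]
  }
  pairs <- t(vapply(roots_a, function(a) c(1 - a, 1 - b_of(a)), numeric(2)))
  keep <- apply(pairs, 1L, function(p_) all(p_ >= -1e-12 & p_ <= 1 + 1e-12))
  pairs <- pairs[keep, , drop = FALSE]
  pairs[pairs < 0] <- 0
  pairs[pairs > 1] <- 1
  colnames(pairs) <- c("epsilon1", "epsilon2")
  n_sol <- nrow(pairs)
  if (n_sol > 0L) {
    slow_first <- which(pairs[, 1L] <= pairs[, 2L])
    primary <- if (length(slow_first)) slow_first[1L] else 1L
    e1 <- pairs[primary, 1L]
    e2 <- pairs[primary, 2L]
    resid <- c(one_year = alpha * (1 - e1) + (1 - alpha) * (1 - e2) - s1,
               five_year = alpha * (1 - e1)^5 + (1 - alpha) * (1 - e2)^5 - s5)
  } else {
    e1 <- e2 <- NA_real_
    resid <- c(one_year = NA_real_, five_year = NA_real_)
  }
  structure(list(epsilon1 = unname(e1), epsilon2 = unname(e2),
                 alpha = alpha, s1 = s1, s5 = s5,
                 residuals = resid, n_solutions = n_sol,
                 all_roots = pairs),
            class = "mover_stayer_fit")
}

#' @export
print.mover_stayer_fit <- function(x, ...) {
  cat("Two-component mover-stayer calibration\n")
  cat(sprintf("  shares: s1Y = %s, s5Y = %s; alpha = %s\n",
              format(x$s1), format(x$s5), format(x$alpha)))
  if (x$n_solutions == 0L) {
    cat("  no admissible (epsilon1, epsilon2) root\n")
  } else {
    cat(sprintf("  epsilon1 = %.6f (tau = %.1f y), epsilon2 = %.6f (tau = %.1f y)\n",
                x$epsilon1, 1 / x$epsilon1, x$epsilon2, 1 / x$epsilon2))
    if (x$n_solutions > 1L) {
      cat("  ", x$n_solutions, "admissible roots (see $all_roots)\n")
    }
  }
  invisible(x)
}

#' @export
coef.mover_stayer_fit <- function(object, ...) {
  c(epsilon1 = object$epsilon1, epsilon2 = object$epsilon2,
    alpha = object$alpha)
}

#' @export
summary.mover_stayer_fit <- function(object, ...) {
  out <- object
  out$one_component_s5 <- object$s1^5
  if (object$n_solutions > 0L) {
    out$implied_s5 <- object$alpha * (1 - object$epsilon1)^5 +
      (1 - object$alpha) * (1 - object$epsilon2)^5
  } else {
    out$implied_s5 <- NA_real_
  }
  class(out) <- "summary.mover_stayer_fit"
  out
}

#' @export
print.summary.mover_stayer_fit <- function(x, ...) {
  print.mover_stayer_fit(x)
  cat(sprintf("  homogeneous extrapolation s1^5 = %.5f (observed s5 = %s)\n",
              x$one_component_s5, format(x$s5)))
  if (!is.na(x$implied_s5)) {
    cat(sprintf("  model five-year share = %.5f; residuals %.2e / %.2e\n",
                x$implied_s5, x$residuals[1], x$residuals[2]))
  }
  invisible(x)
}

#' Stayer curve of a calibrated fit
#'
#' Share of residents who have not changed zone within \eqn{t} years:
#' \eqn{s(t) = \alpha(1-\epsilon_1)^t + (1-\alpha)(1-\epsilon_2)^t}.
#' This is the direct mover-stayer curve; return flows through the
#' kernel are excluded. \code{predict()} on the fit is an alias.
#'
#' @param result a [mover_stayer_fit] with at least one root.
#' @param horizons integer horizons \eqn{\ge 0}, in years.
#' @return named numeric vector of shares, one per horizon.
#' @export
stayer_curve <- function(result, horizons) {
  stopifnot(inherits(result, "mover_stayer_fit"))
  if (result$n_solutions < 1L) stop("fit has no admissible root")
  horizons <- as.integer(horizons)
  if (anyNA(horizons) || any(horizons < 0L)) {
    stop("horizons must be integers >= 0")
  }
  s <- result$alpha * (1 - result$epsilon1)^horizons +
    (1 - result$alpha) * (1 - result$epsilon2)^horizons
  stats::setNames(s, horizons)
}

#' @rdname stayer_curve
#' @param object,... a [mover_stayer_fit]; further arguments ignored.
#' @export
predict.mover_stayer_fit <- function(object, horizons = 0:30, ...) {
  stayer_curve(object, horizons)
}

#' @export
plot.mover_stayer_fit <- function(x, horizons = 0:30, ...) {
  s2 <- stayer_curve(x, horizons)
  s1c <- x$s1^horizons
  graphics::plot(horizons, s2, type = "l", ylim = c(0, 1),
                 xlab = "t (years)", ylab = "stayer share", ...)
  graphics::lines(horizons, s1c, lty = 2)
  graphics::points(c(0, 1, 5), c(1, x$s1, x$s5), pch = 19)
  graphics::legend("topright", bty = "n", lty = c(1, 2, NA), pch = c(NA, NA, 19),
                   legend = c("two-component", "one-component", "data"))
  invisible(x)
}

#' Map the number of calibration solutions
#'
#' Counts admissible \eqn{(\epsilon_1, \epsilon_2)} roots of the
#' two-share system over a grid of \eqn{\alpha} and five-year shares,
#' reproducing the zero/one/two-solution phase structure of the
#' calibration problem.
#'
#' @param s1 one-year stayer share.
#' @param alpha_grid,s5_grid numeric grids in (0, 1).
#' @param ... passed to [mover_stayer_fit()].
#' @return integer matrix, rows indexed by \code{s5_grid}, columns by
#'   \code{alpha_grid}.
#' @export
count_solutions <- function(s1, alpha_grid, s5_grid, ...) {
  stopifnot(all(alpha_grid > 0 & alpha_grid < 1))
  out <- matrix(NA_integer_, length(s5_grid), length(alpha_grid),
                dimnames = list(format(s5_grid), format(alpha_grid)))
  for (i in seq_along(s5_grid)) {
    for (j in seq_along(alpha_grid)) {
      out[i, j] <- if (s5_grid[i] > s1 || s5_grid[i] < 0) {
        0L
      } else {
        mover_stayer_fit(s1, s5_grid[i], alpha_grid[j], ...)$n_solutions
      }
    }
  }
  out
}

#' Homogeneous (one-component) stayer extrapolation
#'
#' With a single relocation frequency the \eqn{t}-year stayer share is
#' \eqn{s_{1Y}^t}; e.g. a 0.9 one-year share extrapolates to
#' \eqn{0.9^5 \approx 0.59} over five years, well below observed
#' five-year shares.
#'
#' @param s1 one-year stayer share in \eqn{[0, 1]}.
#' @param horizon integer horizon \eqn{\ge 0}, years.
#' @return \eqn{s_{1Y}^{horizon}}.
#' @export
one_component_extrapolation <- function(s1, horizon) {
  if (s1 < 0 || s1 > 1) stop("s1 must be in [0, 1]")
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 0L) stop("horizon must be >= 0")
  s1^horizon
}

#' Stayer share under the refractory (immobility) model
#'
#' A rival homogeneous explanation of the five-year gap: after moving, a
#' resident cannot move again for \eqn{\tau} years. The model is a
#' renewal chain over age-since-last-move states \eqn{0..\tau}: ages
#' below \eqn{\tau} never move; at age \eqn{\ge \tau} the per-year move
#' hazard is \eqn{q}, calibrated so that the stationary population's
#' one-year stayer share equals \eqn{s_{1Y}}, which gives
#' \eqn{q = (1-s_{1Y}) / (1 - \tau(1-s_{1Y}))}. The returned share is
#' the stationary-population probability of not moving within the
#' horizon window, computed by powers of the no-move-restricted
#' transition matrix.
#'
#' Because the refractory ages cannot move at all, the movers' hazard
#' must exceed \eqn{1-s_{1Y}}, and the model's five-year stayer share
#' falls below the plain homogeneous \eqn{s_{1Y}^5} — the opposite of
#' what would reconcile the model with observed five-year shares.
#'
#' @param s1 one-year stayer share in (0, 1).
#' @param tau refractory period in whole years, \eqn{\ge 0};
#'   \eqn{\tau = 0} reduces to the homogeneous model.
#' @param horizon window length in whole years, \eqn{\ge 0}.
#' @return stayer share in \eqn{[0, 1]}, with attributes \code{q} (the
#'   calibrated hazard) and \code{age_distribution} (stationary ages).
#' @export
immobility_model_share <- function(s1, tau, horizon) {
  if (!(s1 > 0 && s1 < 1)) stop("s1 must be in (0, 1)")
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 0L) stop("tau must be an integer >= 0")
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 0L) stop("horizon must be >= 0")
  denom <- 1 - tau * (1 - s1)
  q <- if (denom > 0) (1 - s1) / denom else Inf
  if (!(q > 0 && q <= 1)) {
    stop("no feasible hazard: need tau <= s1/(1-s1) = ",
         format(s1 / (1 - s1)), ", got tau = ", tau)
  }
  # stationary age distribution: pi_i = q*c for ages i < tau, pi_tau = c
  cst <- 1 / (1 + tau * q)
  age_pi <- c(rep(q * cst, tau), cst)
  # no-move paths only: age i < tau advances; age tau survives w.p. 1-q
  m <- matrix(0, tau + 1L, tau + 1L)
  if (tau >= 1L) for (i in seq_len(tau)) m[i, i + 1L] <- 1
  m[tau + 1L, tau + 1L] <- 1 - q
  v <- age_pi
  for (s in seq_len(horizon)) v <- as.numeric(v %*% m)
  structure(sum(v), q = q, age_distribution = age_pi)
}
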