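# Independent oracles: kept deliberately separate from the package's own
# code paths so each check has two routes to the same number.

# strip classes and bookkeeping attributes for exact matrix comparison
as_plain <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# brute-force stationary vector by repeated left-multiplication
# (Cesaro mean over the second half makes it valid for periodic chains)
power_iter_oracle <- function(p, iters = 10000L) {
  v <- rep(1 / nrow(p), nrow(p))
  acc <- numeric(nrow(p))
  half <- iters %/% 2L
  for (i in seq_len(iters)) {
    v <- as.numeric(v %*% p)
    if (i > half) acc <- acc + v
  }
  acc / (iters - half)
}

# diagonal of P^t for the symmetric 2-state mover-stayer chain
two_state_stay_prob <- function(epsilon, t) (1 + (1 - 2 * epsilon)^t) / 2

# random row-stochastic matrix (strictly positive, hence primitive)
random_stochastic <- function(n) {
  m <- matrix(stats::runif(n * n, min = 0.01), n, n)
  m / rowSums(m)
}

# quintic-companion oracle for the two-share calibration: expand
# f(a) = alpha*a^5 + (1-alpha)*((s1 - alpha*a)/(1-alpha))^5 - s5
# into monomial coefficients and hand it to polyroot()
polyroot_calibration <- function(s1, s5, alpha) {
  c0 <- s1 / (1 - alpha)
  c1 <- -alpha / (1 - alpha)
  coefs <- numeric(6)
  for (k in 0:5) {
    coefs[k + 1] <- (1 - alpha) * choose(5, k) * c0^(5 - k) * c1^k
  }
  coefs[6] <- coefs[6] + alpha
  coefs[1] <- coefs[1] - s5
  rts <- polyroot(coefs)
  a <- Re(rts[abs(Im(rts)) < 1e-8])
  b <- (s1 - alpha * a) / (1 - alpha)
  ok <- a >= -1e-9 & a <= 1 + 1e-9 & b >= -1e-9 & b <= 1 + 1e-9
  cbind(epsilon1 = 1 - a[ok], epsilon2 = 1 - b[ok])
}

# agent-based Monte-Carlo of the refractory model: ages drawn from the
# stationary renewal distribution, then simulated forward
mc_refractory_share <- function(s1, tau, horizon, n_agents, seed) {
  set.seed(seed)
  q <- (1 - s1) / (1 - tau * (1 - s1))
  cst <- 1 / (1 + tau * q)
  age_pi <- c(rep(q * cst, tau), cst)       # ages 0..tau (tau = cap)
  age <- sample(0:tau, n_agents, replace = TRUE, prob = age_pi)
  moved <- rep(FALSE, n_agents)
  for (y in seq_len(horizon)) {
    mover <- age >= tau & stats::runif(n_agents) < q
    moved <- moved | mover
    age <- ifelse(mover, 0L, pmin(age + 1L, tau))
  }
  share <- mean(!moved)
  se <- sqrt(share * (1 - share) / n_agents)
  list(share = share, se = se)
}
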