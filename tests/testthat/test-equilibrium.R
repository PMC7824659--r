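test_that("stationary distribution matches hand-computable cities", {
  Hs <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2))
  eq <- stationary_distribution(Hs, total = 100)
  expect_equal(unname(as.numeric(eq$x_eq)), c(50, 50))
  expect_false(eq$is_unique)   # periodic chain: primitivity fails

  H3 <- spatial_kernel(matrix(c(0, 0.5, 0.5,
                                1, 0, 0,
                                1, 0, 0), 3, 3, byrow = TRUE))
  eq3 <- stationary_distribution(H3, total = 1)
  expect_equal(unname(as.numeric(eq3$x_eq)), c(0.5, 0.25, 0.25),
               tolerance = 1e-10)
  expect_equal(unname(as.numeric(eq3$x_eq)),
               power_iter_oracle(unclass(H3)), tolerance = 1e-10)
  expect_error(stationary_distribution(matrix(c(0.5, 0.2, 0.3, 0.7), 2, 2)),
               "row-stochastic")
})

test_that("equilibrium is invariant to the relocation frequency", {
  set.seed(13)
  H <- spatial_kernel(random_stochastic(8))
  eqs <- lapply(c(0.05, 0.5, 1.0), function(e) {
    as.numeric(stationary_distribution(relocation_model(e, H), 1)$x_eq)
  })
  expect_equal(eqs[[1]], eqs[[2]], tolerance = 1e-8)
  expect_equal(eqs[[1]], eqs[[3]], tolerance = 1e-8)
  expect_equal(eqs[[1]], as.numeric(stationary_distribution(H, 1)$x_eq),
               tolerance = 1e-8)
})

test_that("eigen route agrees with long power iteration on random kernels", {
  set.seed(17)
  for (n in c(5, 20, 50)) {
    H <- spatial_kernel(random_stochastic(n))
    eq <- stationary_distribution(H, total = 1)
    expect_equal(as.numeric(eq$x_eq), power_iter_oracle(unclass(H)),
                 tolerance = 1e-8)
  }
})

test_that("shared-kernel mixture equilibrium splits as alpha_k * Xeq", {
  H <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2))
  mx <- component_mixture(c(0.3, 0.7), c(0.05, 0.5), H)
  eq <- mixture_equilibrium(mx, total = 100)
  expect_equal(unname(as.numeric(eq$per_component[[1]])), c(15, 15))
  expect_equal(unname(as.numeric(eq$per_component[[2]])), c(35, 35))
  expect_equal(as.numeric(eq$x_eq),
               as.numeric(eq$per_component[[1]]) +
                 as.numeric(eq$per_component[[2]]))
  # single component: just the kernel's equilibrium
  one <- component_mixture(1, 0.3, H)
  expect_equal(unname(as.numeric(mixture_equilibrium(one, 50)$x_eq)), c(25, 25))
})

test_that("opposed absorbing kernels give unit-mass stationary vectors", {
  # H1 sends everyone to zone 1, H2 to zone 2
  H1 <- spatial_kernel(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
  H2 <- spatial_kernel(matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE))
  mx <- component_mixture(c(0.5, 0.5), c(0.3, 0.3), list(H1, H2))
  eq <- mixture_equilibrium(mx, total = 1)
  expect_equal(unname(as.numeric(eq$per_component[[1]])), c(0.5, 0))
  expect_equal(unname(as.numeric(eq$per_component[[2]])), c(0, 0.5))
  expect_equal(unname(as.numeric(eq$x_eq)), c(0.5, 0.5))
  # discrepancy against the aggregate kernel is computable by brute force
  err <- equilibrium_approximation_error(mx, total = 1)
  hhat <- 0.5 * unclass(H1) + 0.5 * unclass(H2)
  expect_equal(as.numeric(err),
               sum(abs(c(0.5, 0.5) - power_iter_oracle(hhat))),
               tolerance = 1e-10)
})

test_that("mixture convergence: any initial split reaches alpha_k * Xeq", {
  lc <- linear_city_kernels(n_zones = 21, beta = 0.1, center = 11)
  mx <- component_mixture(c(0.25, 0.75), c(0.15, 0.4), lc$H1)
  x0 <- population_vector(rep(100, 21))
  # lopsided split: component 1 starts entirely in the first zones
  c1 <- c(rep(100 * 0.25 * 21 / 5, 5), rep(0, 16))
  tr <- evolve(x0, mx, 300, component_states = list(c1, rep(100, 21) - c1))
  eq <- mixture_equilibrium(mx, total = sum(x0))
  for (k in 1:2) {
    expect_lt(max(abs(tr$component_states[[k]][301, ] -
                        as.numeric(eq$per_component[[k]]))),
              1e-6 * sum(x0))
  }
})

test_that("non-primitive kernels are flagged, not rejected", {
  bk <- random_block_kernels(n_zones = 12, set_A = 4:9, seed = 3)
  eq <- stationary_distribution(bk$H1, total = 1)
  expect_false(eq$is_unique)
  # support confined to the positive-column set
  expect_lt(sum(as.numeric(eq$x_eq)[-(4:9)]), 1e-10)
  expect_equal(as.numeric(eq$x_eq), power_iter_oracle(unclass(bk$H1)),
               tolerance = 1e-8)
})

test_that("relaxation diagnostics recover the 2-state spectral rate exactly", {
  eps <- 0.15
  m <- relocation_model(eps, spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2)))
  tr <- evolve(population_vector(c(100, 0)), m, 40)
  de <- relaxation_diagnostics(tr, m)
  expect_equal(de$lambda2, 1 - 2 * eps, tolerance = 1e-12)
  expect_equal(de$fitted_slope, log(1 - 2 * eps), tolerance = 1e-9)
  expect_equal(de$near_equilibrium_ratio, 2 * eps, tolerance = 1e-9)
  # ||Q||/||U|| is 2*eps at every step for this chain
  un <- apply(tr$driving_forces, 1, function(v) sqrt(sum(v^2)))
  qn <- apply(tr$rates, 1, function(v) sqrt(sum(v^2)))
  expect_equal(qn / un[seq_along(qn)], rep(2 * eps, 40), tolerance = 1e-9)
})

test_that("fitted slope matches log|lambda2(P)| on the linear toy city", {
  lc <- linear_city_kernels()
  m <- relocation_model(0.2, lc$H1)
  x0 <- population_vector(seq(1, 99) * 10)
  tr <- evolve(x0, m, 60)
  de <- relaxation_diagnostics(tr, m, window = 20:60)
  expect_lt(abs(de$fitted_slope - de$predicted_slope) /
              abs(de$predicted_slope), 0.02)
  expect_lt(de$fitted_slope, 0)
  # eigendecomposition oracle for lambda2 of P = (1-e)I + eH
  lam_H <- sort(Mod(eigen(unclass(lc$H1), only.values = TRUE)$values),
                decreasing = TRUE)[2]
  expect_equal(de$lambda2, 1 - 0.2 * (1 - lam_H), tolerance = 1e-10)
})

test_that("diagnostics reject degenerate inputs", {
  H <- spatial_kernel(matrix(c(0, 1, 1, 0), 2, 2))
  m <- relocation_model(0.1, H)
  expect_error(relaxation_diagnostics(evolve(population_vector(c(1, 1)), m, 3),
                                      m),
               "at least 5")
  # identity model is not primitive
  m0 <- relocation_model(0, H)
  tr0 <- evolve(population_vector(c(100, 0)), m0, 10)
  expect_error(relaxation_diagnostics(tr0, m0), "primitive")
  # start at equilibrium: nothing to fit
  treq <- evolve(population_vector(c(50, 50)), m, 10)
  expect_error(relaxation_diagnostics(treq, m), "equilibrium")
})
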