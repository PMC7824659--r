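test_that("degenerate shares give the equal-frequency root", {
  for (al in c(0.2, 0.5, 0.9)) {
    fit <- mover_stayer_fit(0.91, 0.91^5, alpha = al)
    expect_gte(fit$n_solutions, 1L)
    # a double root: conditioning limits attainable accuracy to ~sqrt(eps)
    expect_equal(fit$epsilon1, 0.09, tolerance = 1e-5)
    expect_equal(fit$epsilon2, 0.09, tolerance = 1e-5)
  }
})

test_that("Sydney shares at alpha = 0.95 give the slow/fast pair", {
  fit <- mover_stayer_fit(0.91, 0.73, alpha = 0.95)
  expect_equal(fit$n_solutions, 1L)
  expect_equal(fit$epsilon1, 0.051, tolerance = 1e-2)
  expect_equal(fit$epsilon2, 0.83, tolerance = 1e-2)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # independent quintic-companion oracle
  oracle <- polyroot_calibration(0.91, 0.73, 0.95)
  i <- which.min(abs(oracle[, "epsilon1"] - fit$epsilon1))
  expect_equal(fit$epsilon1, unname(oracle[i, "epsilon1"]),
               tolerance = 1e-9)
  expect_equal(fit$epsilon2, unname(oracle[i, "epsilon2"]),
               tolerance = 1e-9)
})

test_that("inadmissible shares are rejected, empty root sets flagged", {
  expect_error(mover_stayer_fit(0.91, 0.95, alpha = 0.9),
               "admissible region")
  expect_error(mover_stayer_fit(0.91, -0.1, alpha = 0.9),
               "admissible region")
  # below the s1^5 floor there can be no admissible root
  fit <- mover_stayer_fit(0.91, 0.3, alpha = 0.5)
  expect_equal(fit$n_solutions, 0L)
  expect_true(is.na(fit$epsilon1))
})

test_that("alpha and 1 - alpha give mirrored roots", {
  set.seed(23)
  for (rep in 1:15) {
    s1 <- runif(1, 0.4, 0.95)
    s5 <- runif(1, s1^5, s1)
    al <- runif(1, 0.1, 0.45)
    f1 <- mover_stayer_fit(s1, s5, al)
    f2 <- mover_stayer_fit(s1, s5, 1 - al)
    expect_equal(f1$n_solutions, f2$n_solutions)
    if (f1$n_solutions > 0) {
      mirrored <- f2$all_roots[, c(2, 1), drop = FALSE]
      reord <- mirrored[order(mirrored[, 1]), , drop = FALSE]
      orig <- f1$all_roots[order(f1$all_roots[, 1]), , drop = FALSE]
      expect_equal(unname(orig), unname(reord), tolerance = 1e-7)
    }
  }
})

test_that("every root satisfies both share equations to 1e-10", {
  set.seed(29)
  for (rep in 1:25) {
    s1 <- runif(1, 0.3, 0.98)
    s5 <- runif(1, s1^5, s1)
    al <- runif(1, 0.05, 0.95)
    fit <- mover_stayer_fit(s1, s5, al)
    if (fit$n_solutions > 0) {
      for (r in seq_len(nrow(fit$all_roots))) {
        e1 <- fit$all_roots[r, 1]; e2 <- fit$all_roots[r, 2]
        expect_lt(abs(al * (1 - e1) + (1 - al) * (1 - e2) - s1), 1e-10)
        expect_lt(abs(al * (1 - e1)^5 + (1 - al) * (1 - e2)^5 - s5), 1e-10)
      }
    }
  }
})

test_that("a root exists somewhere in alpha for every admissible pair", {
  for (s1 in seq(0.3, 0.95, by = 0.13)) {
    # at the s5 = s1 endpoint the unique solution sits at alpha = s1
    alphas <- c(seq(0.05, 0.95, by = 0.05), s1)
    for (s5 in seq(s1^5, s1, length.out = 5)) {
      counts <- vapply(alphas, function(al) {
        mover_stayer_fit(s1, s5, al, n_scan = 2000L)$n_solutions
      }, integer(1))
      expect_gte(max(counts), 1L)
    }
  }
})

test_that("count_solutions maps the zero/one/two-root phases", {
  m <- count_solutions(0.91, alpha_grid = c(0.2, 0.5, 0.95),
                       s5_grid = c(0.5, 0.73, 0.95))
  expect_true(all(m[3, ] == 0L))             # s5 > s1
  expect_gte(m["0.73", "0.95"], 1L)
  expect_gte(min(m["0.73", ]), 0L)
  expect_true(all(count_solutions(0.8, c(0.3, 0.7), 0.8^5) >= 1L))
})

test_that("the stayer curve interpolates its calibration points", {
  fit <- mover_stayer_fit(0.91, 0.73, alpha = 0.95)
  s <- stayer_curve(fit, c(0, 1, 5, 30))
  expect_equal(unname(s[1]), 1)
  expect_equal(unname(s[2]), 0.91, tolerance = 1e-10)
  expect_equal(unname(s[3]), 0.73, tolerance = 1e-10)
  expect_equal(unname(s[4]), 0.2, tolerance = 0.05)
  expect_equal(unname(predict(fit, c(0, 1, 5, 30))), unname(s))
})

test_that("the stayer curve decays monotonically within its envelope", {
  set.seed(31)
  for (rep in 1:10) {
    s1 <- runif(1, 0.5, 0.95)
    s5 <- runif(1, s1^5, s1)
    fit <- mover_stayer_fit(s1, s5, 0.8)
    if (fit$n_solutions == 0 || fit$epsilon2 == 0) next
    s <- stayer_curve(fit, 0:40)
    expect_true(all(diff(s) < 0))
    floor_env <- (1 - max(fit$epsilon1, fit$epsilon2))^(0:40) * 0.2
    expect_true(all(s >= floor_env - 1e-12))
  }
})

test_that("calibrated mixtures respect the convexity (Jensen) floor", {
  set.seed(37)
  for (rep in 1:10) {
    s1 <- runif(1, 0.4, 0.95)
    s5 <- runif(1, s1^5, s1)
    al <- runif(1, 0.1, 0.9)
    fit <- mover_stayer_fit(s1, s5, al)
    if (fit$n_solutions == 0) next
    lhs <- al * (1 - fit$epsilon1)^5 + (1 - al) * (1 - fit$epsilon2)^5
    rhs <- (al * (1 - fit$epsilon1) + (1 - al) * (1 - fit$epsilon2))^5
    expect_gte(lhs, rhs - 1e-12)
  }
})

test_that("homogeneous extrapolation is the plain power of s1", {
  expect_equal(one_component_extrapolation(0.9, 5), 0.59049)
  expect_equal(one_component_extrapolation(1, 17), 1)
  expect_equal(one_component_extrapolation(0.73, 1), 0.73)
  expect_error(one_component_extrapolation(1.2, 5), "s1")
})

test_that("refractory model reduces to homogeneous at tau = 0", {
  for (t in c(0, 1, 5, 12)) {
    expect_equal(as.numeric(immobility_model_share(0.91, 0, t)), 0.91^t,
                 tolerance = 1e-12)
  }
})

test_that("refractory model reproduces s1 at one year for every tau", {
  for (tau in 0:5) {
    expect_equal(as.numeric(immobility_model_share(0.91, tau, 1)), 0.91,
                 tolerance = 1e-12)
  }
})

test_that("refractory five-year share never exceeds the homogeneous one", {
  for (tau in 1:5) {
    expect_lte(as.numeric(immobility_model_share(0.91, tau, 5)),
               0.91^5 + 1e-12)
  }
})

test_that("refractory shares agree with an agent-based simulation", {
  for (tau in c(1, 3)) {
    mc <- mc_refractory_share(0.91, tau, 5, n_agents = 2e5, seed = 101 + tau)
    expect_lt(abs(as.numeric(immobility_model_share(0.91, tau, 5)) - mc$share),
              3 * mc$se)
  }
})

test_that("infeasible refractory periods are refused with the bound", {
  # tau must not exceed s1/(1-s1)
  expect_error(immobility_model_share(0.6, 2, 5), "feasible")
  expect_silent(immobility_model_share(0.6, 1, 5))
})
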