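test_that("identical parameters and seed reproduce trials bit-for-bit", {
  p <- simulation_params(seed = 77)
  a <- simulate_trials(p)
  b <- simulate_trials(p)
  expect_identical(a, b)
  c <- simulate_trials(simulation_params(seed = 78))
  expect_false(identical(a$hr_surrogate, c$hr_surrogate))
})

test_that("the derived true R2 follows the line parameterization", {
  p <- simulation_params(tau1 = 0.4, slope_true = 0.33, resid_sd = 0.066)
  expect_equal(p$r2_true,
               (0.33^2 * 0.4^2) / (0.33^2 * 0.4^2 + 0.066^2))
  expect_equal(simulation_params(slope_true = 0)$r2_true, 0)
  expect_equal(simulation_params(resid_sd = 0)$r2_true, 1)

  # line <-> correlation conversions invert each other
  lc <- line_to_corr(p)
  back <- corr_to_line(p$tau1, lc["tau2"], lc["rho"])
  expect_equal(unname(back["slope"]), p$slope_true, tolerance = 1e-12)
  expect_equal(unname(back["resid_sd"]), p$resid_sd, tolerance = 1e-12)
})

test_that("large simulations match the implied between-trial covariance", {
  p <- simulation_params(n_trials = 10000, tau1 = 0.4, slope_true = 0.33,
                         resid_sd = 0.1, se1_range = c(1e-4, 2e-4),
                         se2_range = c(1e-4, 2e-4), seed = 5)
  eff <- to_effects(simulate_trials(p))
  lc <- line_to_corr(p)
  expect_equal(sd(eff$y1), p$tau1, tolerance = 0.02)
  expect_equal(sd(eff$y2), unname(lc["tau2"]), tolerance = 0.02)
  expect_equal(cov(eff$y1, eff$y2),
               unname(lc["rho"] * p$tau1 * lc["tau2"]), tolerance = 0.02)
  expect_equal(mean(eff$y1), p$beta1, tolerance = 0.02)
})

test_that("degenerate generators produce the analytically forced fits", {
  # on-line data with vanishing errors: downstream correlation is 1
  p <- simulation_params(n_trials = 8, resid_sd = 0, se1_range = c(1e-5, 2e-5),
                         se2_range = c(1e-5, 2e-5), seed = 3)
  eff <- to_effects(simulate_trials(p))
  expect_lt(abs(fit_brma(eff)$r2 - 1), 1e-3)

  # zero true slope: fitted correlation centred at zero across replicates
  rhos <- sapply(1:40, function(i) {
    pp <- simulation_params(n_trials = 12, slope_true = 0, resid_sd = 0.12,
                            se1_range = c(0.02, 0.05), se2_range = c(0.02, 0.05),
                            seed = 1000 + i)
    fit_brma(to_effects(simulate_trials(pp)), method = "ml")$rho
  })
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("a one-replicate experiment reproduces a single simulate-and-fit call", {
  p <- simulation_params(seed = 123)
  rec <- recovery_experiment(p, n_reps = 1, estimator = "likelihood")
  direct <- fit_brma(to_effects(simulate_trials(p)))
  expect_equal(rec$per_rep$r2_hat[1], direct$r2)
  expect_equal(rec$summary$n_failed, 0)
})

test_that("recovery summaries carry bias, RMSE and coverage", {
  p <- simulation_params(n_trials = 12, seed = 9,
                         se1_range = c(0.02, 0.05), se2_range = c(0.02, 0.05))
  rec <- recovery_experiment(p, n_reps = 20, estimator = "shrinkage")
  s <- rec$summary
  expect_equal(s$bias, s$mean_r2 - p$r2_true)
  expect_true(s$rmse >= abs(s$bias) - 1e-12)
  expect_true(is.finite(s$coverage))
  expect_equal(nrow(rec$per_rep), 20L)
})
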