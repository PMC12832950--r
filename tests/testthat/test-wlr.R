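test_that("equal weights reproduce ordinary least squares exactly", {
  eff <- toy_effects(8, seed = 5, se_lo = 0.1, se_hi = 0.1)  # constant se
  fit <- fit_wlr(eff)  # inv_var_true with constant se2 = equal weights
  ols <- lm(y2 ~ y1, data = eff)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$r2_weighted, summary(ols)$r.squared, tolerance = 1e-10)
})

test_that("an exact linear relation is recovered with unit R2", {
  eff <- make_effects(c(-1, 0, 1), rep(0.1, 3), c(-1, 1, 3), rep(0.1, 3))
  fit <- fit_wlr(eff)  # points on y = 2x + 1
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r2_weighted, 1, tolerance = 1e-12)
  expect_equal(fit$residual_scale, 0, tolerance = 1e-20)
  # zero residual scale degenerates the band to the line itself
  pb <- prediction_interval(fit, c(-0.5, 0.7))
  expect_equal(pb$lower, pb$fit, tolerance = 1e-9)
  expect_equal(pb$upper, pb$fit, tolerance = 1e-9)
})

test_that("weighted R2 equals the weighted coefficient of determination", {
  for (seed in c(1, 2, 3)) {
    eff <- toy_effects(9, seed = seed)
    for (ws in c("inv_var_true", "inv_var_sum")) {
      fit <- fit_wlr(eff, ws)
      w <- fit$weights
      res <- eff$y2 - fit$intercept - fit$slope * eff$y1
      ybar <- sum(w * eff$y2) / sum(w)
      r2_det <- 1 - sum(w * res^2) / sum(w * (eff$y2 - ybar)^2)
      expect_equal(fit$r2_weighted, r2_det, tolerance = 1e-10)
    }
  }
})

test_that("degenerate designs and bad weights are rejected", {
  eff <- make_effects(rep(-0.4, 4), rep(0.1, 4), c(-0.2, -0.1, 0, 0.1), rep(0.1, 4))
  expect_error(fit_wlr(eff), "degenerate design")
  good <- toy_effects(6, seed = 2)
  good$n_patients <- NULL
  expect_error(fit_wlr(good, "sample_size"), "n_patients")
})

test_that("R2 interval methods behave and bootstrap is seed-stable", {
  eff <- toy_effects(10, seed = 8)
  fit <- fit_wlr(eff)
  fz <- wlr_r2_interval(fit)
  expect_true(fz$lower >= 0 && fz$upper <= 1 && fz$lower <= fz$upper)
  b1 <- wlr_r2_interval(fit, method = "bootstrap", n_boot = 200, seed = 3)
  b2 <- wlr_r2_interval(fit, method = "bootstrap", n_boot = 200, seed = 3)
  expect_identical(b1, b2)

  # perfectly collinear data: the point estimate is exactly 1
  col <- line_effects(5, slope = 0.4, se1 = 0.05, se2 = 0.05)
  cfit <- fit_wlr(col)
  expect_equal(cfit$r2_weighted, 1, tolerance = 1e-9)

  expect_error(wlr_r2_interval(fit_wlr(toy_effects(3, seed = 1))), "at least 4")
})

test_that("the threshold is where the band's upper limit crosses zero", {
  eff <- fixture_effects("primary")
  fit <- fit_wlr(eff)
  for (band in c("confidence", "prediction")) {
    ste <- compute_ste(fit, band = band)
    expect_true(ste$solvable)
    up <- prediction_interval(fit, ste$x_threshold, band = band)$upper
    expect_lt(abs(up), 1e-8)
    expect_equal(ste$ste_hr, exp(ste$x_threshold))
  }
  # the prediction band is wider, so its threshold is more stringent
  expect_lt(compute_ste(fit, band = "prediction")$ste_hr,
            compute_ste(fit, band = "confidence")$ste_hr)
})

test_that("noiseless threshold solves the line itself and flags HR > 1", {
  x <- seq(-1, -0.1, length.out = 6)
  eff <- make_effects(x, rep(0.1, 6), -0.032 + 0.332 * x, rep(0.1, 6))
  fit <- fit_wlr(eff)
  ste <- compute_ste(fit)
  expect_true(ste$solvable)
  expect_true(ste$exceeds_null)
  expect_equal(ste$ste_hr, exp(0.032 / 0.332), tolerance = 1e-6)
})

test_that("more residual scatter strictly lowers the threshold", {
  eff <- fixture_effects("primary")
  fit <- fit_wlr(eff)
  ste0 <- compute_ste(fit)$ste_hr
  infl <- fit
  for (k in c(1.2, 1.5)) {
    infl$residual_scale <- fit$residual_scale * k
    expect_lt(compute_ste(infl)$ste_hr, ste0)
    ste0 <- compute_ste(infl)$ste_hr
  }
  # with enough scatter the band never excludes the null: no threshold at all
  infl$residual_scale <- fit$residual_scale * 3
  expect_false(compute_ste(infl)$solvable)
})

test_that("non-positive slopes yield an unsolvable threshold", {
  x <- seq(-1, -0.1, length.out = 6)
  eff <- make_effects(x, rep(0.1, 6), 0.2 - 0.3 * x, rep(0.1, 6))
  ste <- compute_ste(fit_wlr(eff))
  expect_false(ste$solvable)
  expect_match(ste$message, "slope")
})
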