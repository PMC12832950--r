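test_that("noiseless collinear trials drive the correlation to one", {
  eff <- line_effects(5, intercept = 0.1, slope = 0.5, se1 = 1e-6, se2 = 1e-6)
  fit <- fit_brma(eff)
  expect_lt(abs(fit$r2 - 1), 1e-4)
  expect_equal(fit$r2, fit$rho^2)
  ln <- implied_line(fit)
  expect_equal(unname(ln["slope"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(ln["intercept"]), 0.1, tolerance = 1e-3)
})

test_that("label swap negates the means and preserves the variance structure", {
  eff <- toy_effects(8, seed = 11)
  neg <- eff
  neg$y1 <- -neg$y1; neg$y2 <- -neg$y2
  a <- fit_brma(eff); b <- fit_brma(neg)
  expect_equal(b$mu1, -a$mu1, tolerance = 1e-5)
  expect_equal(b$mu2, -a$mu2, tolerance = 1e-5)
  expect_equal(b$tau1, a$tau1, tolerance = 1e-5)
  expect_equal(b$tau2, a$tau2, tolerance = 1e-5)
  expect_equal(abs(b$rho), abs(a$rho), tolerance = 1e-5)
  expect_equal(b$r2, a$r2, tolerance = 1e-5)
})

test_that("with vanishing within-trial error the fit recovers sample moments", {
  set.seed(3)
  n <- 6
  y1 <- rnorm(n, -0.4, 0.35)
  y2 <- -0.05 + 0.4 * y1 + rnorm(n, 0, 0.1)
  eff <- make_effects(y1, rep(1e-4, n), y2, rep(1e-4, n))
  S <- cov(cbind(y1, y2))  # (n-1)-denominator

  ml <- fit_brma(eff, method = "ml")
  expect_equal(c(ml$mu1, ml$mu2), c(mean(y1), mean(y2)), tolerance = 1e-3)
  # ML recovers the n-denominator covariance
  expect_equal(ml$tau1^2, S[1, 1] * (n - 1) / n, tolerance = 1e-3)
  expect_equal(ml$tau2^2, S[2, 2] * (n - 1) / n, tolerance = 1e-3)
  expect_equal(ml$rho, S[1, 2] / sqrt(S[1, 1] * S[2, 2]), tolerance = 1e-3)

  # REML recovers the (n-1)-denominator covariance
  reml <- fit_brma(eff, method = "reml")
  expect_equal(reml$tau1^2, S[1, 1], tolerance = 1e-3)
  expect_equal(reml$tau2^2, S[2, 2], tolerance = 1e-3)
})

test_that("fit guards its preconditions", {
  eff <- toy_effects(8, seed = 11)
  expect_error(fit_brma(eff[1:3, ]), "at least 4")
  bad <- eff; bad$se1[1] <- 0
  expect_error(fit_brma(bad), "non-positive SE")
})

test_that("prediction at the pooled mean returns the pooled mean", {
  fit <- fit_brma(toy_effects(8, seed = 11))
  p <- predict_new(fit, y1_new = fit$mu1, se1_new = 0.1, se2_new = 0.1)
  expect_equal(p$mean, fit$mu2)
  expect_true(p$lower < p$mean & p$mean < p$upper)
})

test_that("perfect-surrogate limit transfers the surrogate effect one-to-one", {
  eff <- line_effects(6, intercept = 0, slope = 1, se1 = 1e-6, se2 = 1e-6)
  fit <- fit_brma(eff)
  y1n <- fit$mu1 + 0.2
  p <- predict_new(fit, y1n, se1_new = 1e-8, se2_new = 0)
  expect_equal(p$mean, fit$mu2 + 0.2, tolerance = 1e-3)
  expect_lt(p$var, 1e-4)
})

test_that("conditional prediction matches a Monte-Carlo simulation oracle", {
  fit <- fit_brma(fixture_effects("primary"))
  eff <- fit$effects
  i <- which(eff$trial_id == "PROpel")
  p <- predict_new(fit, eff$y1[i], eff$se1[i], eff$se2[i])

  # simulate observed pairs from the fitted joint law, localize at y1_i
  set.seed(99)
  m <- 2e6
  th1 <- rnorm(m, fit$mu1, fit$tau1)
  th2 <- fit$mu2 + fit$rho * fit$tau2 / fit$tau1 * (th1 - fit$mu1) +
    rnorm(m, 0, fit$tau2 * sqrt(max(1 - fit$rho^2, 0)))
  y1s <- th1 + rnorm(m, 0, eff$se1[i])
  y2s <- th2 + rnorm(m, 0, eff$se2[i])
  keep <- abs(y1s - eff$y1[i]) < 0.01
  expect_gt(sum(keep), 5000)
  expect_equal(mean(y2s[keep]), p$mean, tolerance = 0.01)
  expect_equal(sd(y2s[keep]), sqrt(p$var), tolerance = 0.01)
})

test_that("confidence intervals for R2 are well-formed and seed-stable", {
  fit <- fit_brma(toy_effects(8, seed = 11))
  ci <- r2_interval(fit)
  expect_s3_class(ci, "interval_estimate")
  expect_true(ci$lower >= 0 && ci$upper <= 1)
  expect_true(ci$lower <= fit$r2 && fit$r2 <= ci$upper)

  b1 <- r2_interval(fit, method = "parametric_bootstrap", n_boot = 100, seed = 7)
  b2 <- r2_interval(fit, method = "parametric_bootstrap", n_boot = 100, seed = 7)
  expect_identical(b1, b2)
  b3 <- r2_interval(fit, method = "parametric_bootstrap", n_boot = 100, seed = 8)
  expect_false(identical(b1$lower, b3$lower))
})

test_that("cross-check against an independent multivariate meta-analysis fit", {
  # metafor::rma.mv maximizes the same restricted likelihood; it is the
  # independent oracle, never the implementation
  eff <- toy_effects(8, seed = 11)
  long <- data.frame(
    trial = rep(eff$trial_id, 2),
    outcome = rep(c("surr", "true"), each = nrow(eff)),
    yi = c(eff$y1, eff$y2), vi = c(eff$se1^2, eff$se2^2)
  )
  mv <- metafor::rma.mv(yi, V = diag(long$vi), mods = ~ outcome - 1,
                        random = ~ outcome | trial, struct = "UN",
                        data = long, method = "REML")
  fit <- fit_brma(eff, method = "reml")
  expect_equal(sort(unname(coef(mv))), sort(c(fit$mu1, fit$mu2)),
               tolerance = 1e-3)
  expect_equal(sort(sqrt(mv$tau2)), sort(c(fit$tau1, fit$tau2)),
               tolerance = 1e-3)
  expect_equal(mv$rho, fit$rho, tolerance = 1e-3)
})

test_that("shrinkage estimator stays inside [-1, 1] and matches moments", {
  eff <- fixture_effects("primary")
  sh <- fit_shrinkage(eff)
  expect_true(abs(sh$rho) <= 1)
  expect_equal(sh$r2, sh$rho^2)
  # univariate pooled means agree with direct metafor fits
  f1 <- metafor::rma.uni(yi = eff$y1, sei = eff$se1, method = "DL")
  expect_equal(sh$mu1, unname(coef(f1)[1]))
  expect_equal(sh$tau1, sqrt(f1$tau2))
  # line is the regression through the shrunken pairs
  expect_equal(unname(implied_line(sh)["slope"]),
               unname(coef(lm(sh$blup2 ~ sh$blup1))[2]))
})
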