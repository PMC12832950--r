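#' Shrinkage (empirical-Bayes) estimate of the trial-level correlation
#'
#' The joint likelihood estimate of the between-trial correlation
#' ([fit_brma()]) sits on the boundary \eqn{|\rho| = 1} whenever the
#' observed correlation of the effect estimates exceeds what the estimated
#' between-trial variation can support — a well-documented degeneracy of
#' bivariate meta-analysis at small trial counts, and the situation for the
#' bundled mCRPC data. This estimator takes a stabler two-step route used in
#' trial-level surrogacy practice:
#'
#' 1. fit a univariate random-effects meta-analysis per endpoint
#'    (via [metafor::rma.uni()]; estimator `tau_method`, DerSimonian-Laird
#'    by default);
#' 2. form the empirical-Bayes (BLUP) predictions of each trial's true
#'    effects, which shrink the noisy observed effects toward the pooled
#'    means in proportion to their within-trial error;
#' 3. report the Pearson correlation of the shrunken pairs as the
#'    between-trial correlation, together with the univariate
#'    \eqn{\tau} estimates and pooled means.
#'
#' Shrinkage filters the within-trial sampling noise out of each coordinate
#' before correlating, so the estimate is deattenuated relative to the raw
#' Pearson correlation yet cannot leave \eqn{[-1, 1]}. The implied
#' conditional-mean line ([implied_line()]) is the weighted least-squares
#' line through the shrunken pairs.
#'
#' @param effects an `effect_table`, >= 4 rows.
#' @param tau_method heterogeneity estimator passed to `metafor::rma.uni`
#'   (`"DL"` default; `"REML"`, `"ML"`, ... also accepted).
#' @param level level for the Fisher-z confidence interval of the
#'   correlation (standard error `1/sqrt(n - 3)`).
#' @return object of class `shrinkage_fit` with `mu1`, `mu2`, `tau1`,
#'   `tau2`, `rho`, `r2`, the shrunken effects (`blup1`, `blup2`), the
#'   fitted `line` (intercept, slope) and an `r2_interval` element.
#' @export
fit_shrinkage <- function(effects, tau_method = "DL", level = 0.95) {
  check_effects(effects, min_trials = 4L)
  f1 <- suppressWarnings(
    metafor::rma.uni(yi = effects$y1, sei = effects$se1, method = tau_method)
  )
  f2 <- suppressWarnings(
    metafor::rma.uni(yi = effects$y2, sei = effects$se2, method = tau_method)
  )
  b1 <- metafor::blup(f1)$pred
  b2 <- metafor::blup(f2)$pred
  # degenerate case: zero heterogeneity on an endpoint shrinks every trial
  # to the pooled mean; no between-trial correlation is identifiable
  if (sd(b1) < 1e-12 || sd(b2) < 1e-12) {
    rho <- 0
    line <- c(intercept = unname(coef(f2)[1]), slope = 0)
  } else {
    rho <- cor(b1, b2)
    ls <- lm(b2 ~ b1)
    line <- c(intercept = unname(coef(ls)[1]), slope = unname(coef(ls)[2]))
  }
  n <- nrow(effects)
  ci <- if (n > 3 && abs(rho) < 1) {
    q <- z_level(level)
    z <- atanh(rho)
    se_z <- 1 / sqrt(n - 3)
    rb <- sort(tanh(c(z - q * se_z, z + q * se_z))^2)
    if (sign(tanh(z - q * se_z)) != sign(tanh(z + q * se_z))) rb[1] <- 0
    interval_estimate(rho^2, max(rb[1], 0), min(rb[2], 1), level, "fisher_z")
  } else {
    interval_estimate(rho^2, NA_real_, NA_real_, level, "fisher_z")
  }
  structure(
    list(mu1 = unname(coef(f1)[1]), mu2 = unname(coef(f2)[1]),
         tau1 = sqrt(f1$tau2), tau2 = sqrt(f2$tau2),
         rho = rho, r2 = rho^2,
         blup1 = b1, blup2 = b2, line = line,
         r2_interval = ci, tau_method = tau_method,
         n_trials = n, within_corr = 0, effects = effects),
    class = "shrinkage_fit"
  )
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("Shrinkage (EB) trial-level correlation, %d trials (tau: %s)\n",
              x$n_trials, x$tau_method))
  cat(sprintf("  pooled means: mu1 = %.4f, mu2 = %.4f\n", x$mu1, x$mu2))
  cat(sprintf("  between-trial SDs: tau1 = %.4f, tau2 = %.4f\n", x$tau1, x$tau2))
  cat(sprintf("  correlation of shrunken effects: rho = %.4f (R2 = %.4f)\n",
              x$rho, x$r2))
  cat(sprintf("  line: y2 = %.4f %+.4f y1\n", x$line[1], x$line[2]))
  invisible(x)
}

#' @export
implied_line.shrinkage_fit <- function(fit) {
  fit$line
}
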