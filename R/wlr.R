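#' Inverse-variance weighted linear regression of the true on the surrogate
#' effect
#'
#' Weighted least squares of the true-endpoint log HR (`y2`) on the
#' surrogate log HR (`y1`). The default weights are the inverse variances of
#' the regressand, \eqn{1/se_2^2}; the sum of the two variances or the
#' randomized sample size can be used instead. The reported `r2_weighted` is
#' the squared weighted Pearson correlation of the effect pairs, which for a
#' single-covariate weighted regression coincides with the weighted
#' coefficient of determination (both are computed and asserted equal).
#'
#' @param effects an `effect_table`, >= 3 rows.
#' @param weight_scheme `"inv_var_true"` (1/se2^2, default),
#'   `"inv_var_sum"` (1/(se1^2 + se2^2)) or `"sample_size"` (requires an
#'   `n_patients` column).
#' @return object of class `wlr_fit`: `intercept`, `slope`, `weights`,
#'   `residual_scale` (weighted mean squared error, n - 2 denominator),
#'   `sum_w`, `xbar_w`, `Sxx_w`, `n_trials`, `r2_weighted`.
#' @export
fit_wlr <- function(effects, weight_scheme = c("inv_var_true", "inv_var_sum",
                                               "sample_size")) {
  weight_scheme <- match.arg(weight_scheme)
  check_effects(effects, min_trials = 3L)
  w <- switch(weight_scheme,
    inv_var_true = 1 / effects$se2^2,
    inv_var_sum = 1 / (effects$se1^2 + effects$se2^2),
    sample_size = {
      if (is.null(effects$n_patients))
        stop("sample_size weighting needs an n_patients column", call. = FALSE)
      as.numeric(effects$n_patients)
    }
  )
  if (any(w <= 0) || any(!is.finite(w)))
    stop("weights must be positive and finite", call. = FALSE)
  x <- effects$y1; y <- effects$y2; n <- length(x)
  if (max(x) - min(x) < 1e-12)
    stop("degenerate design: all surrogate effects identical", call. = FALSE)
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  Sxx <- sum(w * (x - xbar)^2)
  Sxy <- sum(w * (x - xbar) * (y - ybar))
  Syy <- sum(w * (y - ybar)^2)
  slope <- Sxy / Sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  s2 <- sum(w * res^2) / (n - 2)
  r2_corr <- Sxy^2 / (Sxx * Syy)
  r2_det <- 1 - sum(w * res^2) / Syy
  stopifnot(abs(r2_corr - r2_det) < 1e-10)
  structure(
    list(intercept = intercept, slope = slope, weights = w,
         weight_scheme = weight_scheme, residual_scale = s2,
         sum_w = sw, xbar_w = xbar, Sxx_w = Sxx, n_trials = n,
         r2_weighted = r2_corr, effects = effects),
    class = "wlr_fit"
  )
}

#' @export
print.wlr_fit <- function(x, ...) {
  cat(sprintf("Weighted linear regression (%s), %d trials\n",
              x$weight_scheme, x$n_trials))
  cat(sprintf("  log(HR_true) = %.4f %+.4f * log(HR_surrogate)\n",
              x$intercept, x$slope))
  cat(sprintf("  weighted R2 = %.4f, residual scale = %.4f\n",
              x$r2_weighted, x$residual_scale))
  invisible(x)
}

#' Confidence interval for the weighted R-squared
#'
#' `"fisher_z"` applies the Fisher transformation to the weighted Pearson
#' correlation with nominal standard error `1/sqrt(n - 3)`. `"bootstrap"`
#' resamples trials with replacement (seeded), refits, and takes the
#' percentile interval of the squared weighted correlation.
#'
#' @param fit a [fit_wlr()] object.
#' @param level confidence level.
#' @param method `"fisher_z"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return an `interval_estimate`.
#' @export
wlr_r2_interval <- function(fit, level = 0.95, method = c("fisher_z", "bootstrap"),
                            n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  n <- fit$n_trials
  if (method == "fisher_z") {
    if (n < 4) stop("fisher_z interval needs at least 4 trials", call. = FALSE)
    r <- sign(fit$slope) * sqrt(fit$r2_weighted)
    if (abs(r) >= 1)
      return(interval_estimate(1, 1, 1, level, "fisher_z"))
    q <- z_level(level)
    z <- atanh(r); se_z <- 1 / sqrt(n - 3)
    rb <- sort(tanh(c(z - q * se_z, z + q * se_z))^2)
    if (sign(tanh(z - q * se_z)) != sign(tanh(z + q * se_z))) rb[1] <- 0
    interval_estimate(fit$r2_weighted, max(rb[1], 0), min(rb[2], 1),
                      level, "fisher_z")
  } else {
    set.seed(seed)
    eff <- fit$effects
    r2s <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      b <- eff[idx, , drop = FALSE]
      b$trial_id <- paste0("b", seq_len(n))
      f <- tryCatch(fit_wlr(b, fit$weight_scheme), error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$r2_weighted
    })
    r2s <- r2s[!is.na(r2s)]
    qs <- quantile(r2s, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    interval_estimate(fit$r2_weighted, max(qs[1], 0), min(qs[2], 1),
                      level, "bootstrap")
  }
}

#' Regression bands of the weighted fit
#'
#' Interval for the true-endpoint effect at surrogate effect `x0`:
#' \deqn{\hat y(x_0) \pm q \sqrt{s^2\left(\frac{1}{w_{new}} + \frac{1}{\sum w} +
#'   \frac{(x_0 - \bar x_w)^2}{S_{xx,w}}\right)}}
#' for the prediction band, where \eqn{s^2} is the weighted residual scale,
#' \eqn{q} a t(n-2) (or normal) quantile, and \eqn{w_{new}} the weight of a
#' hypothetical new trial (`mean_weight`: the mean observed weight;
#' `unit_weight`: 1 on the weighted scale). The confidence band omits the
#' \eqn{1/w_{new}} term and covers the conditional mean only.
#'
#' @param fit a [fit_wlr()] object.
#' @param x0 surrogate log HR value(s).
#' @param level band level.
#' @param band `"prediction"` (default) or `"confidence"`.
#' @param new_weight_rule `"mean_weight"` or `"unit_weight"` (prediction
#'   band only).
#' @param df_rule `"t_nminus2"` (default) or `"normal"`.
#' @return data.frame with columns `x`, `fit`, `lower`, `upper`.
#' @export
prediction_interval <- function(fit, x0, level = 0.95,
                                band = c("prediction", "confidence"),
                                new_weight_rule = c("mean_weight", "unit_weight"),
                                df_rule = c("t_nminus2", "normal")) {
  band <- match.arg(band)
  new_weight_rule <- match.arg(new_weight_rule)
  df_rule <- match.arg(df_rule)
  q <- if (df_rule == "t_nminus2") qt(1 - (1 - level) / 2, fit$n_trials - 2)
       else z_level(level)
  w_new <- if (new_weight_rule == "mean_weight") mean(fit$weights) else 1
  extra <- if (band == "prediction") 1 / w_new else 0
  yhat <- fit$intercept + fit$slope * x0
  hw <- q * sqrt(fit$residual_scale *
                   (extra + 1 / fit$sum_w + (x0 - fit$xbar_w)^2 / fit$Sxx_w))
  data.frame(x = x0, fit = yhat, lower = yhat - hw, upper = yhat + hw)
}

#' Surrogate threshold effect
#'
#' The STE is the largest hazard ratio on the surrogate endpoint at which
#' the upper limit of the regression band for the true-endpoint log HR still
#' touches zero: a new trial whose surrogate effect is convincingly below
#' the STE is predicted to achieve a statistically significant effect on the
#' true endpoint. The threshold is located by root finding on the band's
#' upper limit over HR in `[1e-3, 1]` (the bracket is extended above 1 when
#' the band lies below zero at the null; such a solution is reported with an
#' `exceeds_null` flag rather than as an error).
#'
#' The default band is the **confidence** band for the conditional mean —
#' the threshold then refers to the expected true-endpoint effect of a new
#' trial. The prediction band (adding the scatter of a single new trial) is
#' available via `band = "prediction"` and gives materially smaller
#' thresholds; the methods vignette discusses the choice.
#'
#' @param fit a [fit_wlr()] object with positive slope (beneficial
#'   direction).
#' @param level band level.
#' @param band `"confidence"` (default) or `"prediction"`.
#' @param new_weight_rule,df_rule passed to [prediction_interval()].
#' @return list of class `ste_result`: `ste_hr`, `x_threshold`, `level`,
#'   `band`, `df_rule`, `solvable`, `exceeds_null`.
#' @export
compute_ste <- function(fit, level = 0.95,
                        band = c("confidence", "prediction"),
                        new_weight_rule = c("mean_weight", "unit_weight"),
                        df_rule = c("t_nminus2", "normal")) {
  band <- match.arg(band)
  new_weight_rule <- match.arg(new_weight_rule)
  df_rule <- match.arg(df_rule)
  res <- structure(
    list(ste_hr = NA_real_, x_threshold = NA_real_, level = level,
         band = band, df_rule = df_rule, solvable = FALSE,
         exceeds_null = FALSE, message = NULL),
    class = "ste_result"
  )
  if (fit$slope <= 0) {
    res$message <- "slope not positive; surrogate not in beneficial direction"
    return(res)
  }
  gup <- function(x) prediction_interval(fit, x, level, band,
                                         new_weight_rule, df_rule)$upper
  lo <- log(1e-3)
  if (gup(lo) > 0) {
    res$message <- "band upper limit never crosses zero for HR in (0, 1)"
    return(res)
  }
  hi <- 0
  if (gup(hi) < 0) {
    # band still excludes the null at HR = 1: threshold beyond the null
    hi <- log(10)
    if (gup(hi) < 0) {
      res$message <- "band upper limit never crosses zero"
      return(res)
    }
    res$exceeds_null <- TRUE
  }
  root <- uniroot(gup, c(lo, hi), tol = 1e-12)$root
  res$x_threshold <- root
  res$ste_hr <- exp(root)
  res$solvable <- TRUE
  res
}

#' @export
print.ste_result <- function(x, ...) {
  if (x$solvable) {
    cat(sprintf("Surrogate threshold effect: HR = %.4f (%s band, %g%%, %s)\n",
                x$ste_hr, x$band, 100 * x$level, x$df_rule))
    if (x$exceeds_null)
      cat("  warning: threshold exceeds the null (HR > 1); clinically vacuous\n")
  } else {
    cat("Surrogate threshold effect: not solvable —", x$message, "\n")
  }
  invisible(x)
}
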