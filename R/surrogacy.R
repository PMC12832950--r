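#' Classify correlation strength per IQWiG criteria
#'
#' IQWiG's surrogate-validation thresholds operate on the correlation
#' coefficient R: *high* if the lower limit of the 95% CI satisfies
#' R >= 0.85 (R^2 >= 0.7225); *low* if the upper limit satisfies R <= 0.7
#' (R^2 <= 0.49); *medium* otherwise. The input interval is on the R^2 scale
#' and is converted by square root.
#'
#' @param interval an `interval_estimate` on the R^2 scale, or a numeric
#'   vector `c(lower, upper)`.
#' @return list of class `iqwig_class`: `label` (`"high"`, `"medium"`,
#'   `"low"`) and `rationale`.
#' @export
classify_iqwig <- function(interval) {
  if (inherits(interval, "interval_estimate"))
    bounds <- c(interval$lower, interval$upper)
  else bounds <- as.numeric(interval)
  if (length(bounds) != 2L || any(!is.finite(bounds)) ||
      any(bounds < 0) || any(bounds > 1) || bounds[1] > bounds[2])
    stop("need a valid R^2-scale interval in [0, 1]", call. = FALSE)
  r_lo <- sqrt(bounds[1]); r_hi <- sqrt(bounds[2])
  if (r_lo >= 0.85) {
    label <- "high"
    rationale <- sprintf("lower 95%% limit R = %.3f >= 0.85", r_lo)
  } else if (r_hi <= 0.7) {
    label <- "low"
    rationale <- sprintf("upper 95%% limit R = %.3f <= 0.70", r_hi)
  } else {
    label <- "medium"
    rationale <- sprintf("lower R = %.3f < 0.85 and upper R = %.3f > 0.70",
                         r_lo, r_hi)
  }
  structure(list(label = label, rationale = rationale), class = "iqwig_class")
}

#' @export
print.iqwig_class <- function(x, ...) {
  cat(sprintf("IQWiG correlation strength: %s (%s)\n", x$label, x$rationale))
  invisible(x)
}

#' Flag trials outside the regression band
#'
#' Fits the weighted regression on all supplied trials and flags those whose
#' true-endpoint effect lies outside the `level` band at their surrogate
#' effect. The default band is the prediction band; the confidence band is
#' substantially narrower and flags more trials.
#'
#' @param effects an `effect_table`, >= 4 rows.
#' @param level band level.
#' @param band `"prediction"` (default) or `"confidence"`.
#' @param weight_scheme passed to [fit_wlr()].
#' @return character vector of flagged trial ids.
#' @export
flag_outliers <- function(effects, level = 0.95,
                          band = c("prediction", "confidence"),
                          weight_scheme = "inv_var_true") {
  band <- match.arg(band)
  check_effects(effects, min_trials = 4L)
  fit <- fit_wlr(effects, weight_scheme)
  pb <- prediction_interval(fit, effects$y1, level = level, band = band)
  out <- effects$y2 < pb$lower | effects$y2 > pb$upper
  effects$trial_id[out]
}

#' Analysis options for [run_analysis()]
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' are the package's documented choices: REML likelihood fit with zero
#' within-trial correlation, DerSimonian-Laird shrinkage correlation as the
#' reported trial-level R^2, OS-inverse-variance regression weights,
#' confidence-band STE with t quantiles and mean-weight new trials,
#' prediction-band outlier flagging, likelihood-engine LOOCV without
#' parameter-uncertainty inflation.
#'
#' @param level confidence/prediction level used throughout.
#' @param within_corr within-trial correlation for the likelihood fit.
#' @param brma_method `"reml"` or `"ml"`.
#' @param tau_method heterogeneity estimator for the shrinkage fit.
#' @param weight_scheme regression weights, see [fit_wlr()].
#' @param ste_band,ste_df band and quantile rule for [compute_ste()].
#' @param outlier_band band for [flag_outliers()].
#' @param outlier_ids trial ids excluded by the `sensitivity_2` set.
#' @param loocv_engine,loocv_param_uncertainty LOOCV options, see
#'   [run_loocv()].
#' @param r2_ci_method CI method for the likelihood R^2, see [r2_interval()].
#' @param n_boot,seed bootstrap settings where applicable.
#' @return named list of class `surrogacy_options`.
#' @export
surrogacy_options <- function(level = 0.95, within_corr = 0,
                              brma_method = "reml", tau_method = "DL",
                              weight_scheme = "inv_var_true",
                              ste_band = "confidence", ste_df = "t_nminus2",
                              outlier_band = "prediction",
                              outlier_ids = c("NCT02294461", "ERA 223"),
                              loocv_engine = "likelihood",
                              loocv_param_uncertainty = FALSE,
                              r2_ci_method = "fisher_z",
                              n_boot = 2000L, seed = 1L) {
  structure(
    list(level = level, within_corr = within_corr, brma_method = brma_method,
         tau_method = tau_method, weight_scheme = weight_scheme,
         ste_band = ste_band, ste_df = ste_df, outlier_band = outlier_band,
         outlier_ids = outlier_ids, loocv_engine = loocv_engine,
         loocv_param_uncertainty = loocv_param_uncertainty,
         r2_ci_method = r2_ci_method, n_boot = as.integer(n_boot),
         seed = as.integer(seed)),
    class = "surrogacy_options"
  )
}

#' Run the full trial-level surrogacy analysis on one analysis set
#'
#' Builds the requested analysis set, converts records to log-scale effects
#' and runs every stage: likelihood bivariate fit with R^2 interval,
#' shrinkage correlation (the reported trial-level R^2 and correlation
#' equation; see the methods vignette for why the likelihood estimate alone
#' is not reported as the headline), weighted regression with R^2 interval
#' and correlation equation, surrogate threshold effect, leave-one-out
#' cross-validation, IQWiG classification per method, and outlier flagging.
#' Fully deterministic given `options`.
#'
#' @param records a `trial_table` (e.g. [mcrpc_trials()]).
#' @param set_name `"primary"`, `"sensitivity_1"` or `"sensitivity_2"`.
#' @param options a [surrogacy_options()] list.
#' @return object of class `surrogacy_report`.
#' @export
run_analysis <- function(records, set_name = "primary",
                         options = surrogacy_options()) {
  stopifnot(inherits(options, "surrogacy_options"))
  aset <- build_analysis_set(records, set_name, options$outlier_ids)
  effects <- to_effects(aset$records)

  brma_lik <- fit_brma(effects, within_corr = options$within_corr,
                       method = options$brma_method)
  brma_lik_ci <- r2_interval(brma_lik, level = options$level,
                             method = options$r2_ci_method,
                             n_boot = options$n_boot, seed = options$seed)
  shrink <- fit_shrinkage(effects, tau_method = options$tau_method,
                          level = options$level)
  wlr <- fit_wlr(effects, options$weight_scheme)
  wlr_ci <- wlr_r2_interval(wlr, level = options$level)
  ste <- compute_ste(wlr, level = options$level, band = options$ste_band,
                     df_rule = options$ste_df)
  loocv <- run_loocv(effects, level = options$level,
                     engine = options$loocv_engine,
                     within_corr = options$within_corr,
                     param_uncertainty = options$loocv_param_uncertainty)
  outliers <- flag_outliers(effects, level = options$level,
                            band = options$outlier_band,
                            weight_scheme = options$weight_scheme)

  iq_brma <- classify_iqwig(shrink$r2_interval)
  iq_wlr <- classify_iqwig(wlr_ci)
  overall <- c("low", "medium", "high")[min(
    match(iq_brma$label, c("low", "medium", "high")),
    match(iq_wlr$label, c("low", "medium", "high"))
  )]
  ste_status <- switch(overall,
    high = "not required (high correlation); computed for information",
    medium = "required (medium correlation)",
    low = "not interpretable (low correlation); no surrogacy statement possible")

  structure(
    list(
      analysis_set = aset,
      effects = effects,
      brma = list(
        r2 = shrink$r2,
        r2_interval = shrink$r2_interval,
        equation = implied_line(shrink),
        shrinkage_fit = shrink,
        likelihood_fit = brma_lik,
        likelihood_r2 = brma_lik$r2,
        likelihood_r2_interval = brma_lik_ci,
        iqwig = iq_brma
      ),
      wlr = list(
        r2 = wlr$r2_weighted,
        r2_interval = wlr_ci,
        equation = c(intercept = wlr$intercept, slope = wlr$slope),
        fit = wlr,
        iqwig = iq_wlr
      ),
      iqwig_overall = overall,
      ste = ste,
      ste_status = ste_status,
      loocv = loocv,
      outliers_flagged = outliers,
      options = options,
      version = as.character(utils::packageVersion("surrometa"))
    ),
    class = "surrogacy_report"
  )
}

#' @export
print.surrogacy_report <- function(x, ...) {
  a <- x$analysis_set
  cat(sprintf("Trial-level surrogacy report — %s set (%d trials, %d patients)\n",
              a$name, length(a$included_ids), sum(a$records$n_patients)))
  cat(sprintf("  BRMA (shrinkage) R2: %.2f (%.2f, %.2f); line: y2 = %.3f %+.3f y1 [%s]\n",
              x$brma$r2, x$brma$r2_interval$lower, x$brma$r2_interval$upper,
              x$brma$equation[1], x$brma$equation[2], x$brma$iqwig$label))
  cat(sprintf("  BRMA (likelihood) R2: %.2f (%.2f, %.2f)%s\n",
              x$brma$likelihood_r2, x$brma$likelihood_r2_interval$lower,
              x$brma$likelihood_r2_interval$upper,
              if (abs(x$brma$likelihood_fit$rho) > 0.999) " [boundary]" else ""))
  cat(sprintf("  WLR R2: %.2f (%.2f, %.2f); line: y2 = %.3f %+.3f y1 [%s]\n",
              x$wlr$r2, x$wlr$r2_interval$lower, x$wlr$r2_interval$upper,
              x$wlr$equation[1], x$wlr$equation[2], x$wlr$iqwig$label))
  cat(sprintf("  IQWiG overall: %s\n", x$iqwig_overall))
  if (x$ste$solvable)
    cat(sprintf("  STE: HR = %.2f — %s\n", x$ste$ste_hr, x$ste_status))
  else
    cat(sprintf("  STE: not solvable (%s)\n", x$ste$message))
  cat(sprintf("  LOOCV: %d/%d inside %g%% prediction interval (%.0f%%)\n",
              sum(x$loocv$rows$within[x$loocv$rows$refit_converged]),
              x$loocv$n, 100 * x$loocv$level, 100 * x$loocv$accuracy))
  if (length(x$outliers_flagged))
    cat("  flagged outliers:", paste(x$outliers_flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a surrogacy report to JSON
#'
#' Stable serialization (sorted keys, fixed precision): regenerating the
#' report from identical inputs and options produces byte-identical output.
#'
#' @param report a [run_analysis()] report.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
report_json <- function(report, path = NULL) {
  x <- list(
    analysis_set = list(
      name = report$analysis_set$name,
      included_ids = report$analysis_set$included_ids,
      exclusion_reasons = as.list(report$analysis_set$exclusion_reasons),
      n_trials = length(report$analysis_set$included_ids),
      n_patients = sum(report$analysis_set$records$n_patients)
    ),
    brma = list(
      r2 = report$brma$r2,
      r2_lower = report$brma$r2_interval$lower,
      r2_upper = report$brma$r2_interval$upper,
      intercept = unname(report$brma$equation[1]),
      slope = unname(report$brma$equation[2]),
      likelihood = list(
        mu1 = report$brma$likelihood_fit$mu1,
        mu2 = report$brma$likelihood_fit$mu2,
        tau1 = report$brma$likelihood_fit$tau1,
        tau2 = report$brma$likelihood_fit$tau2,
        rho = report$brma$likelihood_fit$rho,
        r2 = report$brma$likelihood_r2,
        loglik = report$brma$likelihood_fit$loglik,
        method = report$brma$likelihood_fit$method
      ),
      iqwig = report$brma$iqwig$label
    ),
    wlr = list(
      r2 = report$wlr$r2,
      r2_lower = report$wlr$r2_interval$lower,
      r2_upper = report$wlr$r2_interval$upper,
      intercept = unname(report$wlr$equation[1]),
      slope = unname(report$wlr$equation[2]),
      iqwig = report$wlr$iqwig$label
    ),
    iqwig_overall = report$iqwig_overall,
    ste = list(
      ste_hr = report$ste$ste_hr,
      x_threshold = report$ste$x_threshold,
      band = report$ste$band,
      solvable = report$ste$solvable,
      exceeds_null = report$ste$exceeds_null,
      status = report$ste_status
    ),
    loocv = list(
      accuracy = report$loocv$accuracy,
      n = report$loocv$n,
      n_failed = report$loocv$n_failed,
      rows = report$loocv$rows
    ),
    outliers_flagged = report$outliers_flagged,
    trials = report$effects,
    options = unclass(report$options),
    version = report$version
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                           dataframe = "rows", null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
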