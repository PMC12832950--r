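#' Leave-one-out cross-validation of trial-level predictions
#'
#' Each trial is removed in turn; the bivariate model is refitted on the
#' remaining trials and the held-out trial's observed true-endpoint log HR
#' is predicted from its surrogate log HR via [predict_new()] with a
#' `level` prediction interval. The overall accuracy is the proportion of
#' observed effects falling inside their interval. Deterministic given the
#' options.
#'
#' @param effects an `effect_table`, >= 5 rows.
#' @param level prediction-interval level.
#' @param engine `"likelihood"` refits [fit_brma()] (default);
#'   `"shrinkage"` refits [fit_shrinkage()].
#' @param method estimation method passed on (`"reml"`/`"ml"` for the
#'   likelihood engine, a tau estimator such as `"DL"` for shrinkage).
#' @param within_corr within-trial correlation (likelihood engine).
#' @param param_uncertainty inflate intervals by parameter-estimation
#'   uncertainty (likelihood engine only; default FALSE — the plain
#'   conditional predictive variance).
#' @return object of class `loocv_result`: `rows` (data.frame with
#'   `trial_id`, `y2_observed`, `y2_predicted`, `lower`, `upper`, `within`,
#'   `refit_converged`), `accuracy`, `n`, `n_failed`.
#' @export
run_loocv <- function(effects, level = 0.95,
                      engine = c("likelihood", "shrinkage"),
                      method = NULL, within_corr = 0,
                      param_uncertainty = FALSE) {
  engine <- match.arg(engine)
  check_effects(effects, min_trials = 5L)
  if (is.null(method)) method <- if (engine == "likelihood") "reml" else "DL"
  n <- nrow(effects)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- effects[-i, , drop = FALSE]
    fit <- tryCatch(
      if (engine == "likelihood")
        fit_brma(train, within_corr = within_corr, method = method)
      else fit_shrinkage(train, tau_method = method),
      error = function(e) NULL
    )
    ok <- !is.null(fit) && (engine == "shrinkage" || fit$converged)
    if (ok) {
      p <- predict_new(fit, effects$y1[i], effects$se1[i], effects$se2[i],
                       level = level, param_uncertainty = param_uncertainty)
      rows[[i]] <- data.frame(
        trial_id = effects$trial_id[i], y2_observed = effects$y2[i],
        y2_predicted = p$mean, lower = p$lower, upper = p$upper,
        within = effects$y2[i] >= p$lower & effects$y2[i] <= p$upper,
        refit_converged = TRUE, stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- data.frame(
        trial_id = effects$trial_id[i], y2_observed = effects$y2[i],
        y2_predicted = NA_real_, lower = NA_real_, upper = NA_real_,
        within = NA, refit_converged = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  rows <- do.call(rbind, rows)
  n_failed <- sum(!rows$refit_converged)
  if (n_failed > 0)
    warning(sprintf("%d leave-one-out refit(s) failed; excluded from accuracy",
                    n_failed), call. = FALSE)
  ok <- rows$refit_converged
  structure(
    list(rows = rows, accuracy = mean(rows$within[ok]), n = sum(ok),
         n_failed = n_failed, level = level, engine = engine, method = method),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (%s/%s), %d trials\n",
              x$engine, x$method, x$n))
  cat(sprintf("  observed inside %g%% prediction interval: %d/%d (%.0f%%)\n",
              100 * x$level, sum(x$rows$within[x$rows$refit_converged]),
              x$n, 100 * x$accuracy))
  if (x$n_failed) cat(sprintf("  failed refits: %d\n", x$n_failed))
  invisible(x)
}

#' Hazard-ratio-scale table of LOOCV results for plotting
#'
#' @param result a [run_loocv()] result.
#' @return data.frame (trial order preserved) with observed and predicted
#'   HRs and the interval bounds exponentiated to the HR scale.
#' @export
loocv_plot_data <- function(result) {
  r <- result$rows
  data.frame(
    trial_id = r$trial_id,
    hr_observed = exp(r$y2_observed),
    hr_predicted = exp(r$y2_predicted),
    hr_lower = exp(r$lower),
    hr_upper = exp(r$upper),
    within = r$within,
    stringsAsFactors = FALSE
  )
}
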