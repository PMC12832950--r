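#' Scatterplot of the effect pairs with the weighted regression bands
#'
#' Log-log scatter of the per-trial effects, point size proportional to the
#' regression weight, with the weighted regression line and its confidence
#' and prediction bands.
#'
#' @param fit a [fit_wlr()] object.
#' @param level band level.
#' @param label_trials draw trial labels.
#' @return a ggplot object.
#' @importFrom rlang .data
#' @export
plot_correlation <- function(fit, level = 0.95, label_trials = TRUE) {
  eff <- fit$effects
  xs <- seq(min(eff$y1) - 0.15, max(eff$y1) + 0.15, length.out = 200)
  cb <- prediction_interval(fit, xs, level, band = "confidence")
  pb <- prediction_interval(fit, xs, level, band = "prediction")
  dat <- data.frame(eff, w = fit$weights)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$y1, y = .data$y2)) +
    ggplot2::geom_ribbon(data = pb,
                         ggplot2::aes(x = .data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, fill = "grey85") +
    ggplot2::geom_ribbon(data = cb,
                         ggplot2::aes(x = .data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, fill = "grey70") +
    ggplot2::geom_line(data = cb,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::labs(x = "log HR, surrogate endpoint",
                  y = "log HR, true endpoint",
                  title = sprintf("Weighted regression: y2 = %.3f %+.3f y1 (R2 = %.2f)",
                                  fit$intercept, fit$slope, fit$r2_weighted)) +
    ggplot2::theme_minimal()
  if (label_trials)
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$trial_id),
                                vjust = -1, size = 2.8)
  p
}

#' Observed versus predicted hazard ratios from leave-one-out validation
#'
#' @param result a [run_loocv()] result.
#' @return a ggplot object (HR scale, interval bars per trial).
#' @export
plot_loocv <- function(result) {
  d <- loocv_plot_data(result)
  d$trial_id <- factor(d$trial_id, levels = rev(d$trial_id))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$trial_id)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hr_lower,
                                         xmax = .data$hr_upper),
                            height = 0.25, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(x = .data$hr_predicted, shape = "predicted"),
                        size = 2.4, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(x = .data$hr_observed, shape = "observed",
                                     colour = .data$within), size = 2.4) +
    ggplot2::scale_shape_manual(NULL, values = c(observed = 16, predicted = 1)) +
    ggplot2::scale_colour_manual(guide = "none",
                                 values = c(`TRUE` = "black", `FALSE` = "red3")) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = 1, linetype = 3) +
    ggplot2::labs(x = "hazard ratio, true endpoint (log scale)", y = NULL,
                  title = sprintf("Leave-one-out validation: %d/%d inside %g%% interval",
                                  sum(d$within, na.rm = TRUE), result$n,
                                  100 * result$level)) +
    ggplot2::theme_minimal()
}
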