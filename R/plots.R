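# ggplot2 figure builders.

#' Plot a concentration-time profile
#'
#' @param object A `pbpk_profile`.
#' @param log_y Plot the concentration axis on the log scale.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpk_profile <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$conc_ng_ml)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a visual predictive check
#'
#' Shaded 5-95th percentile band, simulated mean and min/max envelope, with
#' the observed profile overlaid as points.
#'
#' @param object A `pbpk_vpc`.
#' @param log_y Log-scale concentration axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpk_vpc <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object$bands, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$min), linetype = "dashed",
                       color = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max), linetype = "dashed",
                       color = "grey50") +
    ggplot2::geom_point(data = object$observed,
                        ggplot2::aes(y = .data$conc_ng_ml), color = "black") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  subtitle = sprintf("%.0f%% of observations within the 5-95%% band",
                                     100 * object$fraction_within_band))
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Goodness-of-fit scatter with the two-fold wedge
#'
#' Predicted against observed PK parameters on log axes, with the identity
#' line and the 0.5-2x acceptance wedge.
#'
#' @param object A `pk_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pk_evaluation <- function(object, ...) {
  df <- dplyr::filter(object$per_profile, .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   color = .data$parameter)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(2), linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = -log10(2), linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Observed", y = "Predicted",
                  caption = "dashed lines: two-fold acceptance window")
}

#' Exposure box plot from a summary table
#'
#' Draws the 5-95th percentile box-whisker comparison of total and unbound
#' AUC across population groups from [exposure_boxplot_table()] output.
#'
#' @param summary_table Output of [exposure_boxplot_table()].
#' @return A ggplot.
#' @export
plot_exposure_boxplot <- function(summary_table) {
  ggplot2::ggplot(summary_table,
                  ggplot2::aes(x = .data$label, fill = .data$metric)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p5, lower = .data$q1, middle = .data$median,
                   upper = .data$q3, ymax = .data$p95),
      stat = "identity", position = ggplot2::position_dodge(width = 0.8),
      width = 0.6
    ) +
    ggplot2::labs(x = NULL, y = "AUC0-inf (ng·h/mL)", fill = NULL)
}
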