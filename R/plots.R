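#' Plot out-of-sample predictions against true MOS
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot: predicted vs true MOS, colored by dataset, with the
#'   identity line and the aggregate R-squared/MAE in the subtitle.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions, ggplot2::aes(
    x = .data$truth, y = .data$pred, colour = .data$dataset_id
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "True MOS", y = "Predicted MOS (out-of-sample)", colour = "Dataset",
      title = sprintf("%s, %s cross-validation", object$model_kind, toupper(object$split)),
      subtitle = sprintf("R² = %.3f, MAE = %.3f", object$r_squared, object$mae)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a correlation-vs-window-length curve
#'
#' @param object A `cc_window_curve` from [cc_window_sensitivity()].
#' @param ... Unused.
#' @return A ggplot of mean CC against window length (log-scaled x).
#' @export
autoplot.cc_window_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_s, y = .data$mean_cc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flagged)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Window length (s)", y = "Mean CC",
      shape = "Single window",
      title = "Correlation inflation with window length"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-trial MOS of a simulated study
#'
#' @param object A `simulated_study`.
#' @param ... Unused.
#' @return A ggplot of MOS per trial, grouped by dataset.
#' @export
autoplot.simulated_study <- function(object, ...) {
  df <- mos_scores(object$ratings) |>
    dplyr::left_join(
      dplyr::select(object$trials, "trial_id", "dataset_id"),
      by = "trial_id"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$trial_id, y = .data$mos, colour = .data$dataset_id
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(~dataset_id, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "MOS", colour = "Dataset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      legend.position = "none"
    )
}
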