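#' Plot a threshold sweep
#'
#' Lines of the four uncertainty metrics against the uncertainty
#' threshold; undefined (NA) metric values are dropped from their line.
#'
#' @param object A `uq_threshold_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uq_threshold_sweep
#' @export
autoplot.uq_threshold_sweep <- function(object, ...) {
  long <- as_tibble(object) |>
    dplyr::select("threshold", "usen", "uspe", "upre", "uacc") |>
    tidyr::pivot_longer(-"threshold", names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "uncertainty threshold", y = "metric value",
      colour = NULL,
      title = "Uncertainty evaluation metrics across thresholds"
    ) +
    ggplot2::theme_minimal()
}

#' Reliability diagram of a calibration result
#'
#' Per-bin accuracy against confidence with the identity line; the
#' distance between bars and the diagonal is what the expected calibration
#' error averages.
#'
#' @param object A `uq_calibration` from [bin_predictions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uq_calibration
#' @export
autoplot.uq_calibration <- function(object, ...) {
  bins <- dplyr::filter(object$bins, .data$count > 0)
  ggplot2::ggplot(bins) +
    ggplot2::geom_col(
      ggplot2::aes((.data$bin_low + .data$bin_high) / 2, .data$acc),
      width = 1 / object$m_bins, fill = "steelblue", alpha = 0.8,
      colour = "grey30"
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "red") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "confidence", y = "accuracy",
      title = sprintf("Reliability diagram (ECE = %.2f%%)",
                      object$ece_percent)
    ) +
    ggplot2::theme_minimal()
}

#' Uncertainty distributions of correct versus incorrect predictions
#'
#' Violin plots of the per-sample uncertainty grouped by prediction
#' correctness.  A useful uncertainty estimator shifts the incorrect group
#' visibly upwards.
#'
#' @param lp A [labeled_predictions()] table.
#' @return A ggplot object.
#' @export
plot_group_uncertainty <- function(lp) {
  lp <- validate_labeled_predictions(lp)
  d <- as_tibble(lp) |>
    dplyr::mutate(group = ifelse(
      .data$predicted_class == .data$true_label, "correct", "incorrect"
    ))
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$uncertainty,
                                  fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.1, fill = "white",
                          show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "predictive uncertainty",
      title = "Uncertainty by prediction correctness"
    ) +
    ggplot2::theme_minimal()
}
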