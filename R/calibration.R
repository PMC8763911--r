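#' Confidence binning and expected calibration error
#'
#' Groups predictions into `M` equal-width confidence bins on `[0, 1]`
#' (left-open, right-closed; the first bin additionally includes 0, so a
#' sample with confidence `p` falls in bin `ceiling(p * M)`).  Within each
#' bin `B_m` the accuracy is the fraction of correct predictions and the
#' confidence is the mean of the per-sample confidences; the expected
#' calibration error is the occupancy-weighted mean absolute gap
#' \deqn{ECE = \sum_m \frac{|B_m|}{n} |acc(B_m) - conf(B_m)|,}
#' with empty bins contributing weight 0 (their accuracy and confidence are
#' reported as `NA`).
#'
#' @param lp A [labeled_predictions()] table with a `confidence` column in
#'   `[0, 1]` (the max of the posterior-mean probabilities, unless another
#'   confidence score was injected explicitly).
#' @param m_bins Number of bins `M` (default 10, the usual
#'   reliability-diagram resolution).
#' @return An object of class `"uq_calibration"`: a list with `bins` (a
#'   tibble with `bin`, `bin_low`, `bin_high`, `count`, `acc`, `conf`,
#'   `gap`), `m_bins`, `n`, and the scalar `ece` (also `ece_percent`).
#' @examples
#' lp <- labeled_predictions(
#'   true_label = rep(0, 10), predicted_class = rep(c(0, 1), c(6, 4)),
#'   uncertainty = rep(0.1, 10), confidence = rep(0.8, 10)
#' )
#' bin_predictions(lp, m_bins = 10) # one occupied bin: |0.6 - 0.8| = 0.2
#' @export
bin_predictions <- function(lp, m_bins = 10L) {
  lp <- validate_labeled_predictions(lp)
  if (m_bins < 1L) abort("`m_bins` must be at least 1")
  conf <- lp$confidence
  if (any(is.na(conf))) {
    abort("calibration requires a `confidence` column without missing values")
  }
  if (any(conf < -1e-12 | conf > 1 + 1e-12)) {
    abort("confidence values must lie in [0, 1]")
  }
  conf <- pmin(pmax(conf, 0), 1)
  correct <- lp$predicted_class == lp$true_label
  bin <- pmax(ceiling(conf * m_bins), 1L)

  edges <- seq(0, 1, length.out = m_bins + 1L)
  count <- tabulate(bin, nbins = m_bins)
  acc <- conf_mean <- rep(NA_real_, m_bins)
  occupied <- which(count > 0L)
  acc[occupied] <- vapply(occupied, function(m) mean(correct[bin == m]),
                          numeric(1))
  conf_mean[occupied] <- vapply(occupied, function(m) mean(conf[bin == m]),
                                numeric(1))
  gap <- abs(acc - conf_mean)
  n <- nrow(lp)
  ece_val <- sum((count[occupied] / n) * gap[occupied])

  structure(
    list(
      bins = tibble(
        bin = seq_len(m_bins),
        bin_low = edges[-(m_bins + 1L)],
        bin_high = edges[-1L],
        count = count,
        acc = acc,
        conf = conf_mean,
        gap = gap
      ),
      m_bins = as.integer(m_bins),
      n = n,
      ece = ece_val,
      ece_percent = 100 * ece_val
    ),
    class = "uq_calibration"
  )
}

#' Expected calibration error
#'
#' Convenience wrapper returning only the ECE scalar of
#' [bin_predictions()], as a fraction in `[0, 1]` (multiply by 100 for the
#' percent scale reliability reports usually print).
#'
#' @inheritParams bin_predictions
#' @return The ECE as a single number in `[0, 1]`.
#' @export
ece <- function(lp, m_bins = 10L) {
  bin_predictions(lp, m_bins = m_bins)$ece
}

#' @export
print.uq_calibration <- function(x, ...) {
  cat(sprintf(
    "<uq_calibration: %d bins over %d predictions, ECE = %.4f (%.2f%%)>\n",
    x$m_bins, x$n, x$ece, x$ece_percent
  ))
  print(x$bins)
  invisible(x)
}

#' Tidy the reliability table of a calibration result
#'
#' @param x A `uq_calibration` object.
#' @param ... Unused.
#' @return The per-bin tibble (`bin`, `bin_low`, `bin_high`, `count`,
#'   `acc`, `conf`, `gap`), sufficient to redraw a reliability diagram.
#' @method tidy uq_calibration
#' @export
tidy.uq_calibration <- function(x, ...) x$bins

#' One-row summary of a calibration result
#'
#' @param x A `uq_calibration` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `m_bins`, `ece`, `ece_percent`.
#' @method glance uq_calibration
#' @export
glance.uq_calibration <- function(x, ...) {
  tibble(n = x$n, m_bins = x$m_bins, ece = x$ece,
         ece_percent = x$ece_percent)
}
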