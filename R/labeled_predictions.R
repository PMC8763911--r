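#' Labelled prediction tables
#'
#' The evaluation half of the package operates on a plain table with one
#' row per prediction: the ground-truth label, the predicted class, a
#' non-negative per-sample uncertainty score (predictive entropy unless the
#' user supplies another score), and optionally the confidence (max of the
#' predicted class probabilities, required for calibration).
#' `labeled_predictions()` builds and validates such a table;
#' `as_labeled_predictions()` attaches ground truth to a posterior summary
#' produced by [summarize_posterior()].
#'
#' @param true_label Integer vector of ground-truth classes in `0:(C-1)`.
#' @param predicted_class Integer vector of predicted classes in `0:(C-1)`.
#' @param uncertainty Non-negative finite per-sample uncertainty scores.
#' @param confidence Optional per-sample confidence in `[0, 1]`.
#' @param n_classes Number of classes `C`; inferred from the labels when
#'   omitted.
#' @param sample_id Optional sample identifiers (defaults to `"s1"...`).
#' @return A tibble of class `"uq_labeled_predictions"` with columns
#'   `sample_id`, `true_label`, `predicted_class`, `uncertainty`,
#'   `confidence` (plus any `prob_c*` columns carried along), and an
#'   `n_classes` attribute.
#' @examples
#' labeled_predictions(
#'   true_label = c(0, 0, 1, 1),
#'   predicted_class = c(0, 1, 1, 0),
#'   uncertainty = c(0.10, 0.50, 0.20, 0.25)
#' )
#' @export
labeled_predictions <- function(true_label, predicted_class, uncertainty,
                                confidence = NULL, n_classes = NULL,
                                sample_id = NULL) {
  n <- length(true_label)
  out <- tibble(
    sample_id = as.character(sample_id %||% paste0("s", seq_len(n))),
    true_label = as.integer(true_label),
    predicted_class = as.integer(predicted_class),
    uncertainty = as.double(uncertainty),
    confidence = if (is.null(confidence)) NA_real_ else as.double(confidence)
  )
  validate_labeled_predictions(out, n_classes = n_classes)
}

#' @rdname labeled_predictions
#' @param summary A `uq_predictive_summary` from [summarize_posterior()].
#' @export
as_labeled_predictions <- function(summary, true_label) {
  stopifnot(inherits(summary, "uq_predictive_summary"))
  probs <- dplyr::select(as_tibble(summary), dplyr::starts_with("prob_c"))
  out <- tibble(
    sample_id = paste0("s", summary$sample),
    true_label = as.integer(true_label),
    predicted_class = summary$predicted_class,
    uncertainty = summary$entropy,
    confidence = summary$confidence
  )
  out <- dplyr::bind_cols(out, probs)
  lp <- validate_labeled_predictions(out, n_classes = ncol(probs))
  attr(lp, "entropy_base") <- attr(summary, "entropy_base")
  attr(lp, "source") <- attr(summary, "source")
  lp
}

validate_labeled_predictions <- function(x, n_classes = NULL) {
  x <- as_tibble(x)
  need <- c("true_label", "predicted_class", "uncertainty")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  n <- nrow(x)
  if (n < 1L) abort("need at least one prediction")
  c_ <- as.integer(n_classes %||%
                     (max(x$true_label, x$predicted_class) + 1L))
  if (c_ < 2L) c_ <- 2L
  bad_lab <- which(
    x$true_label < 0L | x$true_label >= c_ |
      x$predicted_class < 0L | x$predicted_class >= c_
  )
  if (length(bad_lab) > 0) {
    abort(sprintf(
      "row %d: label outside 0..%d", bad_lab[1], c_ - 1L
    ))
  }
  bad_unc <- which(!is.finite(x$uncertainty) | x$uncertainty < 0)
  if (length(bad_unc) > 0) {
    abort(sprintf(
      "row %d: uncertainty must be finite and non-negative", bad_unc[1]
    ))
  }
  if (!"confidence" %in% names(x)) x$confidence <- NA_real_
  conf <- x$confidence[!is.na(x$confidence)]
  if (any(conf < -1e-9 | conf > 1 + 1e-9)) {
    abort("confidence values must lie in [0, 1]")
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- paste0("s", seq_len(n))
  attr(x, "n_classes") <- c_
  if (!inherits(x, "uq_labeled_predictions")) {
    class(x) <- c("uq_labeled_predictions", class(x))
  }
  x
}
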