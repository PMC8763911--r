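#' Predictive entropy of class-probability vectors
#'
#' The entropy of the (posterior-mean) class probabilities,
#' \deqn{PE = -\sum_c p_c \log_b p_c,}
#' with the convention \eqn{0 \log 0 = 0}.  Low entropy means a confident
#' prediction; the maximum, \eqn{\log_b C}, is attained on the uniform
#' vector.  With the default base 2 the binary entropy lies in `[0, 1]`,
#' which keeps threshold grids such as 0.1-0.9 meaningful for two-class
#' problems; natural-log entropy is available via `base = exp(1)`.
#'
#' @param probs A probability vector, or a matrix with one probability
#'   vector per row.  Each vector must be non-negative and sum to 1 within
#'   `1e-6`.
#' @param base Logarithm base, greater than 1.
#' @return A numeric vector of entropies, one per row, in
#'   `[0, log_base(C)]`.
#' @examples
#' predictive_entropy(c(0.5, 0.5)) # 1 bit
#' predictive_entropy(c(1, 0)) # 0
#' predictive_entropy(rbind(c(0.9, 0.1), c(0.6, 0.4)))
#' @export
predictive_entropy <- function(probs, base = 2) {
  if (base <= 1) abort("`base` must be greater than 1")
  p <- check_prob_matrix(probs, what = "probability vector")
  terms <- ifelse(p > 0, p * log(p, base = base), 0)
  pe <- -rowSums(terms)
  pmax(pe, 0)
}

#' The uncertainty confusion matrix
#'
#' Crosses prediction correctness (correct / incorrect) with confidence
#' (certain / uncertain at a threshold) into four outcomes:
#' \describe{
#'   \item{TC (true certainty)}{correct and certain — the model is right
#'     and knows it;}
#'   \item{TU (true uncertainty)}{incorrect and uncertain — the error is
#'     flagged;}
#'   \item{FU (false uncertainty)}{correct but uncertain — a fortunate
#'     outcome, the flag was unnecessary;}
#'   \item{FC (false certainty)}{incorrect and certain — the worst outcome,
#'     a confident error.}
#' }
#' A prediction is uncertain iff its uncertainty strictly exceeds the
#' threshold (ties count as certain, so a threshold at the maximum possible
#' entropy flags nothing).
#'
#' @param lp A [labeled_predictions()] table.
#' @param threshold Finite uncertainty threshold.
#' @return A one-row tibble (class `"uq_uncertainty_confusion"`) with
#'   columns `threshold`, `tc`, `tu`, `fu`, `fc`, `n`; the four counts
#'   partition `n`.
#' @examples
#' lp <- labeled_predictions(
#'   true_label = c(0, 0, 1, 1),
#'   predicted_class = c(0, 1, 1, 0),
#'   uncertainty = c(0.10, 0.50, 0.20, 0.25)
#' )
#' uncertainty_confusion(lp, threshold = 0.3)
#' @export
uncertainty_confusion <- function(lp, threshold) {
  lp <- validate_labeled_predictions(lp)
  if (length(threshold) != 1L || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number")
  }
  correct <- lp$predicted_class == lp$true_label
  uncertain <- lp$uncertainty > threshold
  out <- tibble(
    threshold = as.double(threshold),
    tc = sum(correct & !uncertain),
    tu = sum(!correct & uncertain),
    fu = sum(correct & uncertain),
    fc = sum(!correct & !uncertain),
    n = nrow(lp)
  )
  class(out) <- c("uq_uncertainty_confusion", class(out))
  out
}

#' Uncertainty evaluation metrics from a confusion of certainty
#'
#' The analogues of sensitivity, specificity, precision and accuracy,
#' applied to uncertainty flagging:
#' \deqn{USen = TU / (TU + FC)} the fraction of errors that were flagged;
#' \deqn{USpe = TC / (TC + FU)} the fraction of correct predictions left
#' unflagged;
#' \deqn{UPre = TU / (TU + FU)} the fraction of flags that were errors;
#' \deqn{UAcc = (TU + TC) / n} the fraction of all outcomes on the
#' diagonal.
#' A zero denominator yields `NA` (an explicitly undefined metric), never
#' 0, 1 or an error — a perfect batch has no incorrect predictions for
#' USen to average over.
#'
#' @param uc An `uq_uncertainty_confusion` (one or more rows).
#' @return A tibble with one row per input row: `threshold`, `usen`,
#'   `uspe`, `upre`, `uacc`.
#' @examples
#' lp <- labeled_predictions(
#'   true_label = c(0, 0, 1, 1),
#'   predicted_class = c(0, 1, 1, 0),
#'   uncertainty = c(0.10, 0.50, 0.20, 0.25)
#' )
#' uncertainty_metrics(uncertainty_confusion(lp, 0.3))
#' @export
uncertainty_metrics <- function(uc) {
  stopifnot(all(c("tc", "tu", "fu", "fc", "n") %in% names(uc)))
  if (any(uc$n == 0L)) abort("confusion over zero outcomes")
  if (any(uc$tc + uc$tu + uc$fu + uc$fc != uc$n)) {
    abort("counts tc + tu + fu + fc must equal n")
  }
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble(
    threshold = uc$threshold,
    usen = safe_ratio(uc$tu, uc$tu + uc$fc),
    uspe = safe_ratio(uc$tc, uc$tc + uc$fu),
    upre = safe_ratio(uc$tu, uc$tu + uc$fu),
    uacc = (uc$tu + uc$tc) / uc$n
  )
}

#' Sweep the uncertainty threshold over a grid
#'
#' Recomputes the uncertainty confusion matrix and its four metrics at
#' every threshold of a strictly increasing grid.  The default grid spans
#' 0.1-0.9 in steps of 0.1; 0.3 — a common trade-off point between
#' sensitivity and specificity — is part of it.
#'
#' @param lp A [labeled_predictions()] table.
#' @param thresholds Strictly increasing numeric grid.
#' @return A tibble (class `"uq_threshold_sweep"`) with one row per
#'   threshold and columns `threshold`, `tc`, `tu`, `fu`, `fc`, `n`,
#'   `usen`, `uspe`, `upre`, `uacc`.
#' @export
threshold_sweep <- function(lp, thresholds = seq(0.1, 0.9, by = 0.1)) {
  lp <- validate_labeled_predictions(lp)
  if (length(thresholds) < 1L) abort("`thresholds` must be non-empty")
  if (any(!is.finite(thresholds))) abort("`thresholds` must be finite")
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be strictly increasing")
  }
  rows <- purrr::map(thresholds, function(th) {
    uc <- uncertainty_confusion(lp, th)
    dplyr::bind_cols(uc, uncertainty_metrics(uc)[-1L])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("uq_threshold_sweep", setdiff(class(out),
                                               "uq_uncertainty_confusion"))
  out
}

#' Uncertainty summaries for correct versus incorrect predictions
#'
#' A useful uncertainty estimator assigns systematically higher uncertainty
#' to misclassified samples than to correctly classified ones.  This
#' summary groups predictions by correctness and reports location and
#' spread of the uncertainty (and confidence) within each group, plus the
#' difference of group mean uncertainties (incorrect minus correct).
#'
#' @param lp A [labeled_predictions()] table.
#' @return A tibble (class `"uq_group_summary"`) with one row per group
#'   (`"correct"`, `"incorrect"`): `n`, mean / median / quartiles of
#'   uncertainty and of confidence.  The mean-uncertainty gap is stored in
#'   the `"uncertainty_gap"` attribute (`NA` when a group is empty, in
#'   which case the available group is returned alone with a warning).
#' @export
group_uncertainty_summary <- function(lp) {
  lp <- validate_labeled_predictions(lp)
  lp$group <- ifelse(lp$predicted_class == lp$true_label,
                     "correct", "incorrect")
  out <- as_tibble(lp) |>
    dplyr::group_by(group = factor(.data$group,
                                   levels = c("correct", "incorrect"))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_uncertainty = mean(.data$uncertainty),
      median_uncertainty = median(.data$uncertainty),
      q25_uncertainty = quantile(.data$uncertainty, 0.25, names = FALSE),
      q75_uncertainty = quantile(.data$uncertainty, 0.75, names = FALSE),
      mean_confidence = mean(.data$confidence, na.rm = TRUE),
      median_confidence = median(.data$confidence, na.rm = TRUE),
      q25_confidence = stats::quantile(.data$confidence, 0.25,
                                       names = FALSE, na.rm = TRUE),
      q75_confidence = stats::quantile(.data$confidence, 0.75,
                                       names = FALSE, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = as.character(.data$group))
  gap <- NA_real_
  if (nrow(out) == 2L) {
    gap <- out$mean_uncertainty[out$group == "incorrect"] -
      out$mean_uncertainty[out$group == "correct"]
  } else {
    warn(sprintf(
      "only '%s' predictions present; single-group summary returned",
      out$group[1]
    ))
  }
  attr(out, "uncertainty_gap") <- gap
  class(out) <- c("uq_group_summary", class(out))
  out
}
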