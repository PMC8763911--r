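# Prediction tables travel as CSV (the canonical interchange format here —
# these tables are small) or JSON.  Schema: sample_id, true_label,
# prob_c0..prob_c{C-1}, optional uncertainty.  Row probability sums are
# checked to 1e-4, looser than the in-memory 1e-6 to absorb text
# round-tripping.

guess_format <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

#' Read a prediction table
#'
#' Reads and validates a table of per-sample predictions: `sample_id`,
#' `true_label`, per-class probability columns `prob_c0..prob_c{C-1}`, and
#' optionally `uncertainty`.  The predicted class is the argmax of the
#' probabilities (lowest index on ties) and the confidence their maximum.
#' When the `uncertainty` column is absent it is filled with the predictive
#' entropy of the probabilities and the provenance is recorded in the
#' `uncertainty_source` attribute.
#'
#' @param path File to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @param entropy_base Base used when entropy has to be computed.
#' @return A validated [labeled_predictions()] table (probability columns
#'   retained).
#' @export
read_predictions <- function(path, format = c("auto", "csv", "json"),
                             entropy_base = 2) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- guess_format(path, format)
  raw <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  prediction_table_to_lp(raw, entropy_base = entropy_base,
                         where = basename(path))
}

prediction_table_to_lp <- function(raw, entropy_base = 2, where = "table") {
  prob_cols <- grep("^prob_c[0-9]+$", names(raw), value = TRUE)
  need <- c("sample_id", "true_label")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0 || length(prob_cols) < 2L) {
    abort(sprintf(
      "%s: missing required columns (%s)", where,
      paste(c(miss, if (length(prob_cols) < 2L) "prob_c0..prob_c{C-1}"),
            collapse = ", ")
    ))
  }
  prob_cols <- paste0("prob_c", seq_along(prob_cols) - 1L)
  if (!all(prob_cols %in% names(raw))) {
    abort(sprintf("%s: probability columns must be prob_c0..prob_c{C-1}",
                  where))
  }
  probs <- as.matrix(raw[prob_cols])
  sums <- rowSums(probs)
  bad <- which(abs(sums - 1) > 1e-4 | apply(probs < 0, 1L, any))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: row %d probabilities sum to %.4f (must sum to 1 within 1e-4)",
      where, bad[1], sums[bad[1]]
    ))
  }
  probs <- probs / sums
  c_ <- ncol(probs)
  if (any(raw$true_label < 0 | raw$true_label >= c_)) {
    bad <- which(raw$true_label < 0 | raw$true_label >= c_)[1]
    abort(sprintf("%s: row %d true_label outside 0..%d", where, bad, c_ - 1L))
  }
  had_uncertainty <- "uncertainty" %in% names(raw) &&
    !all(is.na(raw$uncertainty))
  out <- tibble(
    sample_id = as.character(raw$sample_id),
    true_label = as.integer(raw$true_label),
    predicted_class = max.col(probs, ties.method = "first") - 1L,
    uncertainty = if (had_uncertainty) {
      as.double(raw$uncertainty)
    } else {
      predictive_entropy(probs, base = entropy_base)
    },
    confidence = apply(probs, 1L, max)
  )
  out <- dplyr::bind_cols(out, as_tibble(probs))
  lp <- validate_labeled_predictions(out, n_classes = c_)
  attr(lp, "uncertainty_source") <- if (had_uncertainty) {
    "supplied"
  } else {
    sprintf("predictive_entropy(base = %g)", entropy_base)
  }
  attr(lp, "entropy_base") <- entropy_base
  lp
}

#' Write a prediction table
#'
#' Inverse of [read_predictions()]; probabilities and uncertainty are
#' written at full precision so a write/read round trip reproduces the
#' table bit-exactly.
#'
#' @param lp A [labeled_predictions()] table with `prob_c*` columns.
#' @param path Output file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(lp, path, format = c("auto", "csv", "json")) {
  lp <- validate_labeled_predictions(lp)
  format <- guess_format(path, format)
  prob_cols <- grep("^prob_c[0-9]+$", names(lp), value = TRUE)
  if (length(prob_cols) < 2L) {
    abort("prediction table needs prob_c* columns to be serialisable")
  }
  out <- as_tibble(lp)[c("sample_id", "true_label", prob_cols,
                         "uncertainty")]
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Write an evaluation report
#'
#' Serialises any combination of a threshold sweep, a calibration result
#' and a group summary.  JSON reports are a single document with one
#' section per component at full precision (undefined metrics as `null`).
#' CSV reports use `path` as a prefix and write one file per component
#' (`<path>_sweep.csv`, `<path>_calibration.csv`, `<path>_groups.csv`)
#' with numbers at 4 significant digits and undefined metrics as empty
#' cells.  Field order is deterministic, so identical runs produce
#' byte-identical reports.
#'
#' @param results Named list with any of `sweep` (a
#'   [threshold_sweep()]), `calibration` (a [bin_predictions()] result),
#'   `groups` (a [group_uncertainty_summary()]).
#' @param path Output file (JSON) or prefix (CSV).
#' @param format `"csv"` or `"json"`.
#' @return A character vector of the files written, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  sections <- list()
  if (!is.null(results$sweep)) {
    sections$sweep <- as_tibble(results$sweep)
  }
  if (!is.null(results$calibration)) {
    cal <- results$calibration
    sections$calibration <- dplyr::mutate(
      tidy(cal), n = cal$n, ece = cal$ece
    )
  }
  if (!is.null(results$groups)) {
    g <- as_tibble(results$groups)
    g$uncertainty_gap <- attr(results$groups, "uncertainty_gap")
    sections$groups <- g
  }
  if (length(sections) == 0L) abort("nothing to report")

  if (format == "json") {
    jsonlite::write_json(sections, path, digits = NA, na = "null",
                         dataframe = "rows")
    return(invisible(path))
  }
  written <- character(0)
  for (nm in names(sections)) {
    f <- paste0(path, "_", nm, ".csv")
    tab <- dplyr::mutate(sections[[nm]], dplyr::across(
      dplyr::where(is.double), ~ signif(.x, 4)
    ))
    readr::write_csv(tab, f, na = "", progress = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Serialise and restore a fixture classifier
#'
#' Fixture models are small, so their weights, architecture and seeds are
#' stored as plain JSON; `read_classifier()` reconstructs a model whose
#' predictions (deterministic and seeded-stochastic) are identical to the
#' original's.
#'
#' @param model A `"uq_mlp"` classifier.
#' @param path JSON file to write / read.
#' @return `write_classifier()` returns `path` invisibly;
#'   `read_classifier()` returns the restored `"uq_mlp"`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "uq_mlp"))
  payload <- list(
    type = "uq_mlp",
    hidden = model$hidden,
    dropout_rate = model$dropout_rate,
    n_features = model$n_features,
    n_classes = model$n_classes,
    seed = model$seed,
    label = model$label,
    member = model$member,
    validation_accuracy = model$validation_accuracy,
    layers = lapply(model$layers, function(l) {
      list(W = l$W, b = l$b, dim = dim(l$W))
    })
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$type, "uq_mlp")) {
    abort(sprintf("%s does not contain a serialised uq_mlp", path))
  }
  layers <- lapply(seq_along(payload$layers$b), function(l) {
    w <- payload$layers$W[[l]]
    if (!is.matrix(w)) w <- matrix(w, nrow = payload$layers$dim[[l]][1])
    list(W = w, b = as.double(payload$layers$b[[l]]))
  })
  structure(
    list(
      layers = layers,
      hidden = as.integer(payload$hidden),
      dropout_rate = payload$dropout_rate,
      n_features = as.integer(payload$n_features),
      n_classes = as.integer(payload$n_classes),
      supports_stochastic = TRUE,
      seed = payload$seed,
      label = payload$label,
      member = payload$member,
      validation_accuracy = payload$validation_accuracy
    ),
    class = c("uq_mlp", "uq_classifier")
  )
}
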