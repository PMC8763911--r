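#' Run an end-to-end synthetic uncertainty study
#'
#' For one seed: draw a training and an independent test set from a
#' synthetic two-Gaussian task, train the fixture classifier (and, when an
#' ensemble method is requested, an ensemble of fixture classifiers), build
#' the predictive posterior with each requested method, and evaluate the
#' resulting uncertainty estimates — threshold sweep, correct-versus-
#' incorrect group summary, and calibration.
#'
#' @param task A [synthetic_task_spec()]; its `n_samples` is the training
#'   size.
#' @param n_test Test-set size (default 2000).
#' @param methods Any of `"mcd"`, `"ensemble"`, `"emcd"`.
#' @param config [fixture_config()] shared by all trained models.
#' @param n_members Ensemble size for the ensemble / EMCD methods
#'   (default 30).
#' @param passes Monte Carlo passes `T` for MCD and EMCD (default 200).
#' @param entropy_base Entropy base for the uncertainty score (default 2).
#' @param thresholds Threshold grid for the sweep.
#' @param m_bins Calibration bins.
#' @param seed Master seed; data, training and posterior draws all derive
#'   from it, so a study is reproducible end to end.
#' @return An object of class `"uq_study"`: per-method results (each with
#'   `predictions`, `sweep`, `groups`, `calibration`, `test_error`,
#'   `uncertainty_gap`) plus the task, seed and sizes.
#' @examples
#' \donttest{
#' st <- uncertainty_study(
#'   synthetic_task_spec(n_samples = 400, seed = 3),
#'   n_test = 300, methods = "mcd", passes = 50, seed = 3
#' )
#' glance(st)
#' }
#' @export
uncertainty_study <- function(task = synthetic_task_spec(),
                              n_test = 2000L,
                              methods = c("mcd", "ensemble", "emcd"),
                              config = fixture_config(),
                              n_members = 30L,
                              passes = 200L,
                              entropy_base = 2,
                              thresholds = seq(0.1, 0.9, by = 0.1),
                              m_bins = 10L,
                              seed = task$seed) {
  methods <- match.arg(methods, c("mcd", "ensemble", "emcd"),
                       several.ok = TRUE)
  train <- generate_dataset(task, seed = derive_seed(seed, 0L, 2L))
  test <- generate_dataset(task, n_samples = n_test,
                           seed = derive_seed(seed, 0L, 3L))
  fcols <- paste0("x", seq_len(task$n_features))
  x_test <- as_feature_matrix(test[fcols])

  mcd_model <- NULL
  members <- NULL
  if ("mcd" %in% methods) {
    cfg <- config
    cfg$seed <- derive_seed(seed, 0L, 4L)
    mcd_model <- train_fixture_classifier(train[fcols], train$label, cfg)
  }
  if (any(c("ensemble", "emcd") %in% methods)) {
    members <- make_fixture_ensemble(
      train[fcols], train$label, base_config = config,
      n_members = n_members, seed = derive_seed(seed, 0L, 5L)
    )
  }

  evaluate_method <- function(method) {
    ps <- switch(
      method,
      mcd = mc_dropout_posterior(mcd_model, x_test, passes = passes,
                                 seed = derive_seed(seed, 0L, 6L)),
      ensemble = ensemble_posterior(members, x_test),
      emcd = ensemble_mc_dropout_posterior(members, x_test, passes = passes,
                                           seed = derive_seed(seed, 0L, 7L))
    )
    lp <- as_labeled_predictions(
      summarize_posterior(ps, entropy_base = entropy_base), test$label
    )
    groups <- suppressWarnings(group_uncertainty_summary(lp))
    list(
      predictions = lp,
      sweep = threshold_sweep(lp, thresholds),
      groups = groups,
      calibration = bin_predictions(lp, m_bins = m_bins),
      test_error = mean(lp$predicted_class != lp$true_label),
      uncertainty_gap = attr(groups, "uncertainty_gap")
    )
  }

  results <- purrr::map(rlang::set_names(methods), evaluate_method)
  structure(
    list(
      task = task, seed = as.integer(seed), n_train = task$n_samples,
      n_test = as.integer(n_test), n_members = as.integer(n_members),
      passes = as.integer(passes), entropy_base = entropy_base,
      thresholds = thresholds, m_bins = as.integer(m_bins),
      results = results,
      validation_accuracy = if (!is.null(mcd_model)) {
        mcd_model$validation_accuracy
      },
      member_architectures = if (!is.null(members)) {
        lapply(members, function(m) m$hidden)
      }
    ),
    class = "uq_study"
  )
}

#' @export
print.uq_study <- function(x, ...) {
  cat(sprintf(
    "<uq_study: seed %d, %d train / %d test, methods: %s>\n",
    x$seed, x$n_train, x$n_test,
    paste(names(x$results), collapse = ", ")
  ))
  print(glance(x))
  invisible(x)
}

#' One row per method summary of a study
#'
#' @param x A `uq_study`.
#' @param threshold Threshold at which to report the four uncertainty
#'   metrics (must lie on the study's sweep grid; default 0.3).
#' @param ... Unused.
#' @return A tibble with one row per method: `test_error`,
#'   `uncertainty_gap` (mean entropy of misclassified minus correct),
#'   `usen`, `uspe`, `upre`, `uacc` at `threshold`, and `ece`.
#' @method glance uq_study
#' @export
glance.uq_study <- function(x, threshold = 0.3, ...) {
  purrr::imap(x$results, function(res, method) {
    row <- res$sweep[which.min(abs(res$sweep$threshold - threshold)), ]
    tibble(
      method = method,
      test_error = res$test_error,
      uncertainty_gap = res$uncertainty_gap,
      threshold = row$threshold,
      usen = row$usen, uspe = row$uspe, upre = row$upre, uacc = row$uacc,
      ece = res$calibration$ece
    )
  }) |>
    dplyr::bind_rows()
}
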