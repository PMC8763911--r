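# Synthetic two-Gaussian classification tasks.  Isotropic Gaussian classes
# admit a closed-form Bayes error, Phi(-Delta / (2 sigma)) for equal priors,
# which gives every downstream accuracy claim an analytic anchor that a
# real (private) image dataset cannot.

#' Specify a synthetic two-class Gaussian task
#'
#' Samples are drawn from two isotropic Gaussian clouds whose means sit
#' `mean_separation` apart along the first feature axis (at
#' `-mean_separation / 2` and `+mean_separation / 2`), with within-class
#' standard deviation `spread` in every coordinate.  Task difficulty is
#' controlled by the ratio `mean_separation / (2 * spread)`: for equal
#' priors the Bayes error is `pnorm(-mean_separation / (2 * spread))`, so a
#' ratio of 1 gives the moderately hard ~15.9% regime typical of an
#' imperfect medical-image classifier.
#'
#' @param n_samples Number of samples to draw.
#' @param n_features Number of features (at least 1).
#' @param class_priors Two positive priors summing to 1.  The preset
#'   `"cxr-like"` uses `(0.25, 0.75)`, mirroring a screening cohort where
#'   three quarters of the images are positive.
#' @param mean_separation Distance between the class means (non-negative).
#' @param spread Isotropic within-class standard deviation (positive).
#' @param seed Master seed; data generation is deterministic given the spec.
#' @return A list of class `"uq_task_spec"`.
#' @export
synthetic_task_spec <- function(n_samples = 2000L, n_features = 2L,
                                class_priors = c(0.5, 0.5),
                                mean_separation = 2, spread = 1,
                                seed = 1L) {
  if (identical(class_priors, "cxr-like")) class_priors <- c(0.25, 0.75)
  if (n_samples < 1L) abort("`n_samples` must be positive")
  if (n_features < 1L) abort("`n_features` must be at least 1")
  if (length(class_priors) != 2L || any(class_priors <= 0) ||
      abs(sum(class_priors) - 1) > 1e-9) {
    abort("`class_priors` must be two positive numbers summing to 1")
  }
  if (mean_separation < 0) abort("`mean_separation` must be non-negative")
  if (spread <= 0) abort("`spread` must be positive")
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_features = as.integer(n_features),
      class_priors = as.double(class_priors),
      mean_separation = as.double(mean_separation),
      spread = as.double(spread),
      seed = as.integer(seed)
    ),
    class = "uq_task_spec"
  )
}

#' Draw a dataset from a synthetic task specification
#'
#' @param spec A [synthetic_task_spec()].
#' @param n_samples,seed Optional overrides of the spec's sample count and
#'   seed (handy for drawing independent train and test sets from one
#'   task).
#' @return A tibble with feature columns `x1..xd` and an integer `label`
#'   column in `{0, 1}`; bit-identical for identical spec and seed.
#' @examples
#' d <- generate_dataset(synthetic_task_spec(n_samples = 100, seed = 42))
#' table(d$label)
#' @export
generate_dataset <- function(spec, n_samples = NULL, seed = NULL) {
  stopifnot(inherits(spec, "uq_task_spec"))
  n <- as.integer(n_samples %||% spec$n_samples)
  if (n < 1L) abort("`n_samples` must be positive")
  with_local_seed(derive_seed(seed %||% spec$seed, 0L, 0L), {
    label <- as.integer(runif(n) < spec$class_priors[2])
    centers <- c(-0.5, 0.5) * spec$mean_separation
    x <- matrix(rnorm(n * spec$n_features, sd = spec$spread),
                nrow = n)
    x[, 1] <- x[, 1] + centers[label + 1L]
    colnames(x) <- paste0("x", seq_len(spec$n_features))
    out <- as_tibble(x)
    out$label <- label
    out
  })
}

#' Closed-form Bayes error of a synthetic task
#'
#' For equal priors and isotropic classes the optimal rule is the midpoint
#' hyperplane and its error is `pnorm(-mean_separation / (2 * spread))`.
#'
#' @param spec A [synthetic_task_spec()] with equal priors.
#' @return The minimum achievable misclassification rate.
#' @export
bayes_error <- function(spec) {
  stopifnot(inherits(spec, "uq_task_spec"))
  if (abs(spec$class_priors[1] - spec$class_priors[2]) > 1e-9) {
    abort(paste(
      "closed-form Bayes error is only available for equal priors;",
      "this spec has unequal class priors"
    ))
  }
  pnorm(-spec$mean_separation / (2 * spec$spread))
}

#' Configuration of the fixture classifier
#'
#' Desk-scale defaults for the dropout multilayer perceptron used as a
#' fixture: two hidden layers of 32 and 16 units, dropout 0.25, 200 epochs
#' of Adam at learning rate 0.001, a 75/25 train/validation split.
#' `hidden_ranges` gives the per-layer `(min, max)` width ranges from which
#' ensemble-member architectures are drawn (the number of hidden layers is
#' drawn uniformly from 2 or 3).
#'
#' @param hidden Hidden-layer widths of a single fixture model.
#' @param dropout_rate Dropout probability on hidden activations.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param validation_split Held-out fraction for validation accuracy.
#' @param hidden_ranges List of `(min, max)` width ranges for random
#'   architecture draws in [make_fixture_ensemble()].
#' @param seed Master seed for training.
#' @return A list of class `"uq_fixture_config"`.
#' @export
fixture_config <- function(hidden = c(32L, 16L), dropout_rate = 0.25,
                           epochs = 200L, learning_rate = 1e-3,
                           batch_size = 256L, validation_split = 0.25,
                           hidden_ranges = list(c(16L, 64L), c(8L, 32L),
                                                c(4L, 16L)),
                           seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1)")
  }
  if (epochs < 1L) abort("`epochs` must be at least 1")
  structure(
    list(
      hidden = as.integer(hidden), dropout_rate = dropout_rate,
      epochs = as.integer(epochs), learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      validation_split = validation_split,
      hidden_ranges = hidden_ranges, seed = as.integer(seed)
    ),
    class = "uq_fixture_config"
  )
}

#' Train a fixture dropout classifier on a synthetic task
#'
#' A thin wrapper around [fit_dropout_mlp()] using a
#' [fixture_config()]; the result satisfies the stochastic-classifier
#' contract (dropout stays active under `stochastic = TRUE`), so it can be
#' sampled by all three posterior approximations.
#'
#' @param features Feature matrix or data frame (e.g. the `x*` columns of
#'   [generate_dataset()]).
#' @param labels Integer labels in `0:(C-1)`; at least two classes must be
#'   present.
#' @param config A [fixture_config()].
#' @return A trained `"uq_mlp"` classifier.
#' @export
train_fixture_classifier <- function(features, labels,
                                     config = fixture_config()) {
  stopifnot(inherits(config, "uq_fixture_config"))
  fit_dropout_mlp(
    features, labels,
    hidden = config$hidden,
    dropout_rate = config$dropout_rate,
    epochs = config$epochs,
    batch_size = config$batch_size,
    learning_rate = config$learning_rate,
    validation_split = config$validation_split,
    seed = config$seed
  )
}

#' Train an ensemble of fixture classifiers
#'
#' Members differ by a random architecture draw (number of hidden layers
#' uniform on \{2, 3\}, per-layer widths uniform on the configured
#' `hidden_ranges`) and by their initialisation/shuffling/dropout seed, all
#' derived from one master seed.  Each member records its drawn
#' architecture in its metadata.
#'
#' @inheritParams train_fixture_classifier
#' @param base_config A [fixture_config()]; its width ranges, dropout,
#'   epochs and optimiser settings are shared by all members.
#' @param n_members Ensemble size (default 30).
#' @param seed Master seed for architecture draws and member training.
#' @return A list of `n_members` trained `"uq_mlp"` classifiers.
#' @export
make_fixture_ensemble <- function(features, labels,
                                  base_config = fixture_config(),
                                  n_members = 30L, seed = 1L) {
  stopifnot(inherits(base_config, "uq_fixture_config"))
  if (n_members < 1L) abort("`n_members` must be at least 1")
  archs <- with_local_seed(derive_seed(seed, 0L, 1L), {
    lapply(seq_len(n_members), function(i) {
      depth <- sample(2:3, 1L)
      vapply(seq_len(depth), function(l) {
        r <- base_config$hidden_ranges[[min(l, length(base_config$hidden_ranges))]]
        sample(r[1]:r[2], 1L)
      }, integer(1))
    })
  })
  lapply(seq_len(n_members), function(i) {
    member_config <- base_config
    member_config$hidden <- archs[[i]]
    member_config$seed <- derive_seed(seed, i, 0L)
    m <- train_fixture_classifier(features, labels, member_config)
    m$member <- i
    m
  })
}
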