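#' Posterior samples from stochastic forward passes or ensemble members
#'
#' The predictive posterior of a classifier is approximated by a stack of
#' class-probability draws: `T` Monte Carlo dropout passes
#' ([mc_dropout_posterior()]), one deterministic pass per ensemble member
#' ([ensemble_posterior()]), or `members * T` passes
#' ([ensemble_mc_dropout_posterior()]).  The stack is stored, not streamed:
#' at desk scale the `S x N x C` array is small and keeps every draw
#' available for averaging, variance estimation and independent re-checking.
#'
#' @param samples Numeric array of shape `(S, N, C)`: draws by samples by
#'   classes, every `(draw, sample)` row a probability vector.
#' @param draw_labels Tibble with one row per draw (columns `draw`, `member`,
#'   `pass`).
#' @param source One of `"mcd"`, `"ensemble"`, `"emcd"`.
#' @param seed Master seed the draws were taken under (`NA` for
#'   deterministic ensembles).
#' @return An object of class `"uq_posterior_samples"`.
#' @keywords internal
new_posterior_samples <- function(samples, draw_labels, source, seed = NA) {
  stopifnot(length(dim(samples)) == 3L)
  s <- dim(samples)[1]
  n <- dim(samples)[2]
  c_ <- dim(samples)[3]
  if (s < 1L || c_ < 2L) abort("need at least 1 draw and 2 classes")
  # (s, n, c) layout flattens to an (s*n) x c matrix without copying twice
  flat <- matrix(samples, nrow = s * n, ncol = c_)
  check_prob_matrix(flat, what = "posterior draw")
  structure(
    list(
      samples = samples,
      draw_labels = draw_labels,
      source = match.arg(source, c("mcd", "ensemble", "emcd")),
      seed = seed
    ),
    class = "uq_posterior_samples"
  )
}

#' @export
print.uq_posterior_samples <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "<uq_posterior_samples: %s, %d draws x %d samples x %d classes>\n",
    x$source, d[1], d[2], d[3]
  ))
  invisible(x)
}

#' @export
dim.uq_posterior_samples <- function(x) dim(x$samples)

#' Tidy a posterior-sample stack into long format
#'
#' @param x A `uq_posterior_samples` object.
#' @param ... Unused.
#' @return A tibble with columns `draw`, `member`, `pass`, `sample`,
#'   `class`, `prob`.
#' @method tidy uq_posterior_samples
#' @export
tidy.uq_posterior_samples <- function(x, ...) {
  d <- dim(x$samples)
  out <- tidyr::expand_grid(
    class = 0:(d[3] - 1L),
    sample = seq_len(d[2]),
    draw = seq_len(d[1])
  )
  out$prob <- as.vector(x$samples)
  dplyr::left_join(out, x$draw_labels, by = "draw") |>
    dplyr::select("draw", "member", "pass", "sample", "class", "prob") |>
    dplyr::arrange(.data$draw, .data$sample, .data$class)
}

collect_draws <- function(draw_fn, n_draws, n, c_) {
  samples <- array(NA_real_, dim = c(n_draws, n, c_))
  for (s in seq_len(n_draws)) samples[s, , ] <- draw_fn(s)
  samples
}

#' Monte Carlo dropout posterior
#'
#' Approximates the predictive posterior by `T` stochastic forward passes
#' with dropout kept active at test time; the posterior mean over passes is
#' the predictive probability and its spread the predictive uncertainty.
#'
#' @param model A classifier honouring the stochastic-classifier contract
#'   with `supports_stochastic(model)` true.
#' @param inputs Feature matrix (one row per sample).
#' @param passes Number of Monte Carlo forward passes `T` (default 200).
#' @param seed Master seed; pass `t` runs under an independent stream
#'   derived from `(seed, t)`, so results do not depend on batch
#'   partitioning.
#' @return A `uq_posterior_samples` object with `S = passes` draws and
#'   `source = "mcd"`.
#' @examples
#' task <- synthetic_task_spec(n_samples = 200, mean_separation = 2, seed = 1)
#' d <- generate_dataset(task)
#' fit <- fit_dropout_mlp(d[1:2], d$label, epochs = 20, seed = 1)
#' ps <- mc_dropout_posterior(fit, d[1:2], passes = 20, seed = 1)
#' summarize_posterior(ps)
#' @export
mc_dropout_posterior <- function(model, inputs, passes = 200L, seed = 1L) {
  if (!supports_stochastic(model)) {
    abort(paste(
      "Monte Carlo dropout requires a stochastic model, but",
      "`supports_stochastic(model)` is FALSE; repeated stochastic passes",
      "would not differ"
    ))
  }
  if (passes < 1L) abort("`passes` must be a positive integer")
  inputs <- as_feature_matrix(inputs)
  samples <- collect_draws(
    function(t) predict_proba(model, inputs, stochastic = TRUE,
                              seed = derive_seed(seed, 0L, t)),
    passes, nrow(inputs), n_classes(model)
  )
  new_posterior_samples(
    samples,
    tibble(draw = seq_len(passes), member = 1L, pass = seq_len(passes)),
    source = "mcd", seed = seed
  )
}

#' Deep-ensemble posterior
#'
#' Evaluates every ensemble member once, deterministically; the mean of the
#' member probabilities is the predictive probability.
#'
#' @param models List of classifiers with identical `n_classes`.
#' @param inputs Feature matrix.
#' @return A `uq_posterior_samples` object with one draw per member and
#'   `source = "ensemble"`.
#' @export
ensemble_posterior <- function(models, inputs) {
  if (!is.list(models) || length(models) < 1L) {
    abort("`models` must be a non-empty list of classifiers")
  }
  ncs <- vapply(models, n_classes, integer(1))
  if (length(unique(ncs)) != 1L) {
    abort("ensemble members disagree on the number of classes")
  }
  inputs <- as_feature_matrix(inputs)
  n_mem <- length(models)
  samples <- collect_draws(
    function(i) predict_proba(models[[i]], inputs, stochastic = FALSE),
    n_mem, nrow(inputs), ncs[1]
  )
  new_posterior_samples(
    samples,
    tibble(draw = seq_len(n_mem), member = seq_len(n_mem), pass = 1L),
    source = "ensemble", seed = NA
  )
}

#' Ensemble Monte Carlo dropout posterior
#'
#' Combines ensembling with Monte Carlo dropout: every member is evaluated
#' by `T` stochastic forward passes and the grand mean over all
#' `members * T` draws is the predictive probability.  With a single member
#' this reduces draw-for-draw to [mc_dropout_posterior()]; with
#' dropout-free members it reduces to [ensemble_posterior()].
#'
#' @inheritParams mc_dropout_posterior
#' @param models List of stochastic classifiers with identical `n_classes`.
#' @return A `uq_posterior_samples` object with `S = members * passes`
#'   draws, labelled by `(member, pass)`, and `source = "emcd"`.
#' @export
ensemble_mc_dropout_posterior <- function(models, inputs, passes = 200L,
                                          seed = 1L) {
  if (!is.list(models) || length(models) < 1L) {
    abort("`models` must be a non-empty list of classifiers")
  }
  ncs <- vapply(models, n_classes, integer(1))
  if (length(unique(ncs)) != 1L) {
    abort("ensemble members disagree on the number of classes")
  }
  for (m in models) {
    if (!supports_stochastic(m)) {
      abort(paste(
        "all ensemble members must be stochastic for ensemble MC dropout,",
        "but a member has `supports_stochastic` FALSE"
      ))
    }
  }
  if (passes < 1L) abort("`passes` must be a positive integer")
  inputs <- as_feature_matrix(inputs)
  n_mem <- length(models)
  labels <- tidyr::expand_grid(member = seq_len(n_mem),
                               pass = seq_len(passes))
  labels$draw <- seq_len(nrow(labels))
  samples <- collect_draws(
    function(s) {
      i <- labels$member[s]
      t <- labels$pass[s]
      predict_proba(models[[i]], inputs, stochastic = TRUE,
                    seed = derive_seed(seed, i - 1L, t))
    },
    nrow(labels), nrow(inputs), ncs[1]
  )
  new_posterior_samples(
    samples, labels[c("draw", "member", "pass")],
    source = "emcd", seed = seed
  )
}

#' Summarise a posterior-sample stack per input sample
#'
#' Reduces the draw stack to per-sample predictive quantities: the
#' posterior-mean probabilities, the predicted class (argmax of the mean,
#' lowest index on exact ties), the confidence (max of the mean), the
#' predictive entropy of the mean, and the across-draw variance of each
#' class probability.
#'
#' @param ps A `uq_posterior_samples` object.
#' @param entropy_base Logarithm base for the predictive entropy; the
#'   default 2 makes binary entropy range over `[0, 1]`.
#' @return A tibble (class `"uq_predictive_summary"`) with one row per
#'   input sample: `sample`, `predicted_class`, `confidence`, `entropy`,
#'   then `prob_c*` (posterior-mean probabilities) and `var_c*`
#'   (across-draw variance, 0 when there is a single draw).  The entropy
#'   base and draw source are stored as attributes.
#' @export
summarize_posterior <- function(ps, entropy_base = 2) {
  stopifnot(inherits(ps, "uq_posterior_samples"))
  d <- dim(ps$samples)
  s <- d[1]
  mean_probs <- colMeans(ps$samples, dims = 1L)
  mean_sq <- colMeans(ps$samples^2, dims = 1L)
  var_probs <- if (s > 1L) {
    (mean_sq - mean_probs^2) * s / (s - 1)
  } else {
    mean_probs * 0
  }
  var_probs <- pmax(var_probs, 0) # guard tiny negative rounding
  mean_probs <- mean_probs / rowSums(mean_probs)

  out <- tibble(
    sample = seq_len(d[2]),
    predicted_class = max.col(mean_probs, ties.method = "first") - 1L,
    confidence = apply(mean_probs, 1L, max),
    entropy = predictive_entropy(mean_probs, base = entropy_base)
  )
  colnames(mean_probs) <- paste0("prob_c", 0:(d[3] - 1L))
  colnames(var_probs) <- paste0("var_c", 0:(d[3] - 1L))
  out <- dplyr::bind_cols(out, as_tibble(mean_probs), as_tibble(var_probs))
  attr(out, "entropy_base") <- entropy_base
  attr(out, "source") <- ps$source
  class(out) <- c("uq_predictive_summary", class(out))
  out
}
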