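# A small fully connected classifier with dropout, trained by Adam on the
# cross-entropy loss (compute kernel in src/mlp_core.cpp).  It exists so the
# posterior machinery can be exercised end to end on synthetic tasks:
# dropout stays available at inference, which is what makes Monte Carlo
# sampling of the predictive posterior possible.  Real convolutional models
# are plugged in through the same stochastic-classifier contract instead.

# Evaluate the RNG-dependent `code` under `seed`, then restore the caller's
# RNG state so model evaluation never perturbs user simulations.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build and train a dropout multilayer-perceptron classifier
#'
#' Trains a small fully connected network (ReLU activations, softmax output,
#' dropout on the hidden layers) on labelled feature vectors, minimising
#' cross-entropy with the Adam optimiser.  Dropout remains available at
#' inference (`stochastic = TRUE` in [predict_proba()]), so the model
#' satisfies the stochastic-classifier contract and can be sampled by
#' [mc_dropout_posterior()].
#'
#' @param x Feature matrix, one row per sample.
#' @param y Integer class labels in `0:(C-1)` (or a factor).
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout_rate Dropout probability on hidden activations, in `[0, 1)`.
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size (capped at the training-set size).
#' @param learning_rate Adam step size.
#' @param validation_split Fraction of rows held out for validation
#'   accuracy; the default 0.25 keeps a 75/25 train/validation split.
#' @param seed Master seed for initialisation, shuffling and dropout masks.
#' @return An object of class `"uq_mlp"` (also `"uq_classifier"`), with a
#'   `validation_accuracy` element when `validation_split > 0`.
#' @export
fit_dropout_mlp <- function(x, y, hidden = c(32L, 16L), dropout_rate = 0.25,
                            epochs = 200L, batch_size = 256L,
                            learning_rate = 1e-3, validation_split = 0.25,
                            seed = 1L) {
  x <- as_feature_matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    abort("training labels contain a single class; need at least 2")
  }
  if (any(classes < 0L)) abort("labels must be integers 0..C-1")
  n_class <- max(classes) + 1L
  stopifnot(
    dropout_rate >= 0, dropout_rate < 1, epochs >= 1,
    nrow(x) == length(y)
  )

  with_local_seed(derive_seed(seed, 0L, 0L), {
    n <- nrow(x)
    idx <- sample.int(n)
    n_val <- floor(validation_split * n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    # guard: keep both classes in the training fold
    if (length(unique(y[tr_idx])) < 2L) tr_idx <- idx
    xt <- x[tr_idx, , drop = FALSE]
    onehot <- diag(n_class)[y[tr_idx] + 1L, , drop = FALSE]

    layers <- mlp_train_cpp(
      xt, onehot,
      layer_sizes = c(ncol(x), as.integer(hidden), n_class),
      dropout_rate = dropout_rate, epochs = as.integer(epochs),
      batch_size = as.integer(min(batch_size, nrow(xt))),
      learning_rate = learning_rate
    )

    model <- structure(
      list(
        layers = layers,
        hidden = as.integer(hidden),
        dropout_rate = dropout_rate,
        n_features = ncol(x),
        n_classes = n_class,
        supports_stochastic = TRUE,
        seed = as.integer(seed),
        label = sprintf("dropout_mlp(%s, p=%.2f)",
                        paste(hidden, collapse = "-"), dropout_rate)
      ),
      class = c("uq_mlp", "uq_classifier")
    )
    if (length(val_idx) > 0) {
      pv <- predict_proba(model, x[val_idx, , drop = FALSE])
      model$validation_accuracy <-
        mean((max.col(pv, ties.method = "first") - 1L) == y[val_idx])
    }
    model
  })
}

#' @export
predict_proba.uq_mlp <- function(object, x, stochastic = FALSE, seed = NULL,
                                 ...) {
  x <- as_feature_matrix(x)
  if (ncol(x) != object$n_features) {
    abort(sprintf("expected %d features, got %d", object$n_features, ncol(x)))
  }
  if (!stochastic) {
    return(mlp_forward_cpp(object$layers, x, object$dropout_rate, FALSE))
  }
  if (is.null(seed)) {
    return(mlp_forward_cpp(object$layers, x, object$dropout_rate, TRUE))
  }
  with_local_seed(seed, {
    mlp_forward_cpp(object$layers, x, object$dropout_rate, TRUE)
  })
}
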