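#' The stochastic-classifier contract
#'
#' Posterior approximation in this package is model-agnostic: any object can
#' be used as a classifier provided it answers [predict_proba()] with a
#' row-stochastic matrix of class probabilities, reports its number of
#' classes via [n_classes()], and declares via [supports_stochastic()]
#' whether repeated stochastic calls can differ (e.g. dropout kept active at
#' inference).  The contract requires that
#' \itemize{
#'   \item every returned row is non-negative and sums to 1 (within 1e-6);
#'   \item with `stochastic = FALSE`, repeated calls on identical inputs are
#'     identical;
#'   \item with a fixed `seed`, stochastic calls are reproducible.
#' }
#'
#' `stochastic_classifier()` wraps a plain R function into an object
#' honouring the contract, which is convenient for plugging in external
#' models (or trivial test doubles).
#'
#' @param predict_fn A function `(x, stochastic, seed)` returning an
#'   `nrow(x)` by `n_classes` probability matrix.
#' @param n_classes Number of classes (integer, at least 2).
#' @param supports_stochastic Whether stochastic forward passes can differ
#'   from the deterministic output.
#' @param label Optional human-readable label.
#' @return An object of class `"uq_classifier"`.
#' @examples
#' coin <- stochastic_classifier(
#'   function(x, stochastic, seed) {
#'     matrix(0.5, nrow = nrow(x), ncol = 2)
#'   },
#'   n_classes = 2, supports_stochastic = FALSE
#' )
#' predict_proba(coin, matrix(0, 3, 1))
#' @export
stochastic_classifier <- function(predict_fn, n_classes,
                                  supports_stochastic = FALSE,
                                  label = "custom") {
  stopifnot(is.function(predict_fn), n_classes >= 2)
  structure(
    list(
      predict_fn = predict_fn,
      n_classes = as.integer(n_classes),
      supports_stochastic = isTRUE(supports_stochastic),
      label = label
    ),
    class = c("uq_fn_classifier", "uq_classifier")
  )
}

#' Class probabilities from a classifier
#'
#' @param object A classifier honouring the stochastic-classifier contract.
#' @param x Feature matrix (or data frame of numeric features), one row per
#'   sample.
#' @param stochastic If `TRUE`, perform a stochastic forward pass (dropout
#'   active); requires `supports_stochastic(object)`.
#' @param seed Integer seed making a stochastic pass reproducible; ignored
#'   for deterministic passes.
#' @param ... Passed on to methods.
#' @return A numeric matrix with one row per sample and one column per
#'   class; rows sum to 1.
#' @export
predict_proba <- function(object, x, stochastic = FALSE, seed = NULL, ...) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.uq_fn_classifier <- function(object, x, stochastic = FALSE,
                                           seed = NULL, ...) {
  x <- as_feature_matrix(x)
  p <- object$predict_fn(x, stochastic, seed)
  check_prob_matrix(p, what = sprintf("classifier '%s' output", object$label))
}

#' @rdname predict_proba
#' @export
n_classes <- function(object) UseMethod("n_classes")

#' @export
n_classes.uq_classifier <- function(object) object$n_classes

#' @rdname predict_proba
#' @export
supports_stochastic <- function(object) UseMethod("supports_stochastic")

#' @export
supports_stochastic.uq_classifier <- function(object) {
  isTRUE(object$supports_stochastic)
}

#' @export
print.uq_classifier <- function(x, ...) {
  cat(sprintf(
    "<uq_classifier: %s, %d classes, %s>\n",
    x$label %||% class(x)[1], n_classes(x),
    if (supports_stochastic(x)) "stochastic" else "deterministic"
  ))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[vapply(x, is.numeric, logical(1))]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  x
}
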