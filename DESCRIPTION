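Package: uqeval
Title: Uncertainty Quantification and Objective Evaluation for Probabilistic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates the predictive posterior of a classifier by Monte
    Carlo dropout, deep ensembling, or ensemble Monte Carlo dropout; scores
    predictive uncertainty by the entropy of the posterior-mean class
    probabilities; and evaluates those uncertainty estimates objectively via
    the uncertainty confusion matrix (true/false certainty and uncertainty)
    with its derived sensitivity, specificity, precision and accuracy
    metrics, threshold sweeps, and the expected calibration error. Includes
    a synthetic two-Gaussian task generator with closed-form Bayes error and
    a small dropout multilayer-perceptron fixture classifier, so the whole
    pipeline is exercisable end to end without external data, plus CSV/JSON
    prediction-table readers, report writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
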