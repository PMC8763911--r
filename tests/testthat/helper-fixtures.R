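# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately written as explicit per-sample loops so they share no code
# path with the vectorised implementations they check.

# -- classifiers --------------------------------------------------------------

constant_classifier <- function(probs, stochastic = FALSE) {
  probs <- as.double(probs)
  stochastic_classifier(
    function(x, stoch, seed) {
      matrix(probs, nrow = nrow(x), ncol = length(probs), byrow = TRUE)
    },
    n_classes = length(probs), supports_stochastic = stochastic,
    label = "constant"
  )
}

# a small trained dropout network on an easy task; cheap to build
fixture_mlp <- function(seed = 1, dropout_rate = 0.25, n = 300,
                        epochs = 30) {
  d <- generate_dataset(synthetic_task_spec(n_samples = n, seed = seed))
  fit_dropout_mlp(d[1:2], d$label, hidden = c(8L, 4L),
                  dropout_rate = dropout_rate, epochs = epochs, seed = seed)
}

fixture_inputs <- function(n = 20, seed = 7) {
  with_seed_restore(seed, matrix(rnorm(n * 2), ncol = 2))
}

with_seed_restore <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# -- the four-sample worked example ------------------------------------------

enumerated_lp <- function() {
  labeled_predictions(
    true_label = c(0L, 0L, 1L, 1L),
    predicted_class = c(0L, 1L, 1L, 0L),
    uncertainty = c(0.10, 0.50, 0.20, 0.25)
  )
}

# random labelled-prediction tables for property tests
random_lp <- function(n, n_class = 2L, seed = 1, with_conf = TRUE) {
  with_seed_restore(seed, {
    labeled_predictions(
      true_label = sample(0:(n_class - 1L), n, replace = TRUE),
      predicted_class = sample(0:(n_class - 1L), n, replace = TRUE),
      uncertainty = runif(n, 0, log2(n_class)),
      confidence = if (with_conf) runif(n, 1 / n_class, 1),
      n_classes = n_class
    )
  })
}

random_prob_stack <- function(s, n, c_, seed = 1) {
  with_seed_restore(seed, {
    a <- array(runif(s * n * c_, 0.05, 1), dim = c(s, n, c_))
    for (i in seq_len(s)) {
      for (j in seq_len(n)) a[i, j, ] <- a[i, j, ] / sum(a[i, j, ])
    }
    a
  })
}

# -- brute-force oracles ------------------------------------------------------

oracle_entropy <- function(p, base = 2) {
  total <- 0
  for (v in p) if (v > 0) total <- total - v * log(v, base = base)
  total
}

oracle_confusion <- function(lp, threshold) {
  counts <- c(tc = 0L, tu = 0L, fu = 0L, fc = 0L)
  for (i in seq_len(nrow(lp))) {
    correct <- lp$predicted_class[i] == lp$true_label[i]
    uncertain <- lp$uncertainty[i] > threshold
    key <- if (correct && !uncertain) {
      "tc"
    } else if (!correct && uncertain) {
      "tu"
    } else if (correct && uncertain) {
      "fu"
    } else {
      "fc"
    }
    counts[key] <- counts[key] + 1L
  }
  counts
}

oracle_metrics <- function(counts) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(
    usen = div(counts[["tu"]], counts[["tu"]] + counts[["fc"]]),
    uspe = div(counts[["tc"]], counts[["tc"]] + counts[["fu"]]),
    upre = div(counts[["tu"]], counts[["tu"]] + counts[["fu"]]),
    uacc = (counts[["tu"]] + counts[["tc"]]) / sum(counts)
  )
}

oracle_ece <- function(lp, m_bins) {
  n <- nrow(lp)
  acc_sum <- conf_sum <- cnt <- rep(0, m_bins)
  for (i in seq_len(n)) {
    p <- lp$confidence[i]
    b <- max(1L, ceiling(p * m_bins))
    cnt[b] <- cnt[b] + 1
    conf_sum[b] <- conf_sum[b] + p
    acc_sum[b] <- acc_sum[b] +
      as.integer(lp$predicted_class[i] == lp$true_label[i])
  }
  total <- 0
  for (b in seq_len(m_bins)) {
    if (cnt[b] > 0) {
      total <- total + (cnt[b] / n) * abs(acc_sum[b] / cnt[b] -
                                            conf_sum[b] / cnt[b])
    }
  }
  total
}
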