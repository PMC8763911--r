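test_that("predictive entropy matches direct evaluation and its bounds", {
  expect_equal(predictive_entropy(c(0.5, 0.5)), 1)
  expect_equal(predictive_entropy(c(1, 0)), 0)
  expect_equal(predictive_entropy(c(1, 0), base = exp(1)), 0)
  expect_equal(predictive_entropy(c(0.9, 0.1)),
               -0.9 * log2(0.9) - 0.1 * log2(0.1))

  # uniform vector attains the log-base-C bound exactly
  for (c_ in 2:5) {
    u <- rep(1 / c_, c_)
    expect_equal(predictive_entropy(u), log2(c_))
    expect_equal(predictive_entropy(u, base = exp(1)), log(c_))
  }

  # random vectors stay within [0, log_base C] and match the hand loop
  for (s in 1:20) {
    p <- with_seed_restore(s, {
      v <- runif(4)
      v / sum(v)
    })
    pe <- predictive_entropy(p)
    expect_gte(pe, 0)
    expect_lte(pe, log2(4))
    expect_equal(pe, oracle_entropy(p))
  }

  expect_error(predictive_entropy(c(0.5, 0.4)), "sums to")
  expect_error(predictive_entropy(c(0.5, 0.5), base = 1), "base")
})

test_that("the uncertainty confusion matrix sorts the four outcomes correctly", {
  uc <- uncertainty_confusion(enumerated_lp(), threshold = 0.3)
  expect_equal(uc$tc, 2L)
  expect_equal(uc$tu, 1L)
  expect_equal(uc$fu, 0L)
  expect_equal(uc$fc, 1L)

  perfect <- labeled_predictions(
    true_label = rep(0L, 5), predicted_class = rep(0L, 5),
    uncertainty = rep(0, 5)
  )
  uc2 <- uncertainty_confusion(perfect, 0.3)
  expect_equal(unlist(uc2[c("tc", "tu", "fu", "fc")]),
               c(tc = 5L, tu = 0L, fu = 0L, fc = 0L))

  # threshold at/above the maximum possible uncertainty flags nothing
  lp <- random_lp(40, seed = 3)
  uc3 <- uncertainty_confusion(lp, max(lp$uncertainty))
  expect_equal(uc3$tu, 0L)
  expect_equal(uc3$fu, 0L)
})

test_that("the four uncertainty metrics follow their defining ratios", {
  um <- uncertainty_metrics(uncertainty_confusion(enumerated_lp(), 0.3))
  expect_equal(um$usen, 0.5)
  expect_equal(um$uspe, 1)
  expect_equal(um$upre, 1)
  expect_equal(um$uacc, 0.75)

  # no incorrect predictions: USen undefined, never 0/1/error
  perfect <- labeled_predictions(
    true_label = rep(0L, 4), predicted_class = rep(0L, 4),
    uncertainty = rep(0, 4)
  )
  um2 <- uncertainty_metrics(uncertainty_confusion(perfect, 0.3))
  expect_true(is.na(um2$usen))
  expect_true(is.na(um2$upre))
  expect_equal(um2$uspe, 1)
  expect_equal(um2$uacc, 1)

  # perfect self-awareness: FU = FC = 0 with TU, TC > 0
  aware <- labeled_predictions(
    true_label = c(0L, 0L, 1L), predicted_class = c(0L, 1L, 1L),
    uncertainty = c(0.1, 0.9, 0.05)
  )
  um3 <- uncertainty_metrics(uncertainty_confusion(aware, 0.5))
  expect_equal(um3$usen, 1)
  expect_equal(um3$uspe, 1)
  expect_equal(um3$uacc, 1)

  bad <- uncertainty_confusion(perfect, 0.3)
  bad$n <- 0L
  expect_error(uncertainty_metrics(bad), "zero")
})

test_that("confusion counts agree with a per-sample loop on random instances", {
  for (s in 1:10) {
    n_class <- 2L + s %% 2L
    lp <- random_lp(5 + (s * 7) %% 46, n_class, seed = 100 + s)
    for (th in c(0.1, 0.3, 0.7)) {
      uc <- uncertainty_confusion(lp, th)
      counts <- oracle_confusion(lp, th)
      expect_equal(unlist(uc[c("tc", "tu", "fu", "fc")]),
                   counts, ignore_attr = TRUE)
      expect_equal(unlist(uncertainty_metrics(uc)[c("usen", "uspe",
                                                    "upre", "uacc")]),
                   oracle_metrics(counts), ignore_attr = TRUE)
    }
  }
})

test_that("threshold sweeps are consistent, monotone and conserving", {
  lp <- random_lp(60, seed = 9)
  sw <- threshold_sweep(lp)
  expect_equal(nrow(sw), 9)
  expect_equal(sw$threshold, seq(0.1, 0.9, by = 0.1))

  # single-point grid equals direct computation
  sw03 <- threshold_sweep(lp, 0.3)
  expect_equal(sw03$usen, uncertainty_metrics(
    uncertainty_confusion(lp, 0.3)
  )$usen)

  accuracy <- mean(lp$predicted_class == lp$true_label)
  for (s in 1:15) {
    lp_i <- random_lp(30, seed = 200 + s)
    sw_i <- threshold_sweep(lp_i)
    # partition and the accuracy link at every threshold
    expect_true(all(sw_i$tc + sw_i$tu + sw_i$fu + sw_i$fc == nrow(lp_i)))
    expect_true(all(abs((sw_i$tc + sw_i$fu) / sw_i$n -
                          mean(lp_i$predicted_class == lp_i$true_label))
                    < 1e-12))
    # flagged set shrinks with the threshold
    expect_true(all(diff(sw_i$usen[!is.na(sw_i$usen)]) <= 1e-12))
    expect_true(all(diff(sw_i$uspe[!is.na(sw_i$uspe)]) >= -1e-12))
  }

  # constant uncertainty: rows split into two identical blocks around u*
  lp_const <- labeled_predictions(
    true_label = c(0L, 1L, 0L, 1L), predicted_class = c(0L, 1L, 1L, 0L),
    uncertainty = rep(0.45, 4)
  )
  sw_c <- threshold_sweep(lp_const)
  below <- sw_c[sw_c$threshold < 0.45, -1]
  above <- sw_c[sw_c$threshold >= 0.45, -1]
  expect_true(all(vapply(seq_len(nrow(below)), function(i) {
    isTRUE(all.equal(below[i, ], below[1, ], check.attributes = FALSE))
  }, logical(1))))
  expect_true(all(vapply(seq_len(nrow(above)), function(i) {
    isTRUE(all.equal(above[i, ], above[1, ], check.attributes = FALSE))
  }, logical(1))))

  expect_error(threshold_sweep(lp, c(0.3, 0.2)), "increasing")
  expect_error(threshold_sweep(lp, numeric(0)), "non-empty")
})

test_that("group summaries separate correct and incorrect predictions", {
  lp <- labeled_predictions(
    true_label = c(0L, 0L, 1L), predicted_class = c(0L, 0L, 0L),
    uncertainty = c(0.1, 0.2, 0.5)
  )
  g <- group_uncertainty_summary(lp)
  expect_equal(g$mean_uncertainty[g$group == "correct"], 0.15)
  expect_equal(g$mean_uncertainty[g$group == "incorrect"], 0.5)
  expect_equal(attr(g, "uncertainty_gap"), 0.35)

  # all uncertainties equal: zero gap
  lp_eq <- labeled_predictions(
    true_label = c(0L, 1L), predicted_class = c(0L, 0L),
    uncertainty = c(0.3, 0.3)
  )
  expect_equal(attr(group_uncertainty_summary(lp_eq), "uncertainty_gap"), 0)

  # single group: returned alone, flagged
  perfect <- labeled_predictions(
    true_label = c(0L, 1L), predicted_class = c(0L, 1L),
    uncertainty = c(0.1, 0.2)
  )
  expect_warning(g1 <- group_uncertainty_summary(perfect), "correct")
  expect_equal(nrow(g1), 1)
  expect_true(is.na(attr(g1, "uncertainty_gap")))
})
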