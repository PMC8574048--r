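test_that("overall PPV/NPV from the reference FIT-stratified counts", {
  counts <- reference_screening_fit_counts()
  ch <- cohort_from_counts(counts)
  g <- group_outcomes(ch, "primary_screening")
  fit <- ch$fit_result[g$index]
  set.seed(71)
  scores <- runif(length(g$label))  # irrelevant at extreme thresholds

  # everyone test-positive in the FIT-positive stratum: PPV = case prevalence
  pos <- fit == "positive"
  pv <- predictive_values(scores[pos], g$label[pos], threshold = -1)
  expect_equal(pv$ppv, (309 + 212 + 69) / 1242, tolerance = 1e-12)
  expect_equal(round(pv$ppv, 2), 0.48)

  # everyone test-negative in the FIT-negative stratum: NPV = control share
  neg <- fit == "negative"
  pv <- predictive_values(scores[neg], g$label[neg], threshold = 2)
  expect_equal(pv$npv, (226 + 78) / 362, tolerance = 1e-12)
  expect_equal(round(pv$npv, 2), 0.84)
})

test_that("a threshold below the minimum score returns the prevalence", {
  set.seed(72)
  labels <- runif(300) < 0.3
  scores <- rnorm(300, 133, 7)
  pv <- predictive_values(scores, labels, min(scores) - 1)
  expect_equal(pv$ppv, mean(labels))
  expect_true(is.na(pv$npv))
  expect_equal(pv$n_test_neg, 0)
})

test_that("the PPV/NPV accounting identity holds at every threshold", {
  set.seed(73)
  labels <- runif(500) < 0.4
  scores <- rnorm(500, 133, 7) + labels
  curve <- predictive_curve(scores, labels)
  ok <- !is.na(curve$ppv) & !is.na(curve$npv)
  cases <- curve$ppv[ok] * curve$n_test_pos[ok] +
    (1 - curve$npv[ok]) * curve$n_test_neg[ok]
  expect_equal(cases, rep(sum(labels), sum(ok)), tolerance = 1e-9)
  # test-positive fraction decreases as the threshold rises
  expect_true(all(diff(curve$n_test_pos) <= 0))
})

test_that("Wilson intervals bracket the estimate and match prop.test", {
  pv <- predictive_values(c(1, 1, 2, 2, 3, 3), c(TRUE, FALSE, TRUE, FALSE,
                                                 TRUE, TRUE), 2)
  expect_true(pv$ppv_low <= pv$ppv && pv$ppv <= pv$ppv_high)
  ref <- suppressWarnings(prop.test(3, 4, correct = FALSE))$conf.int
  expect_equal(c(pv$ppv_low, pv$ppv_high), as.numeric(ref), tolerance = 1e-9)
})

test_that("labels independent of the score give a flat PPV near prevalence", {
  set.seed(74)
  labels <- runif(4000) < 0.35
  scores <- rnorm(4000, 133, 7)
  curve <- predictive_curve(scores, labels,
                            thresholds = seq(125, 140, by = 5))
  expect_true(all(abs(curve$ppv - 0.35) < 0.05, na.rm = TRUE))
})

test_that("degenerate equal scores collapse to a single informative threshold", {
  labels <- rep(c(TRUE, FALSE), 10)
  curve <- predictive_curve(rep(5, 20), labels)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$ppv, 0.5)
})

test_that("population weighting of stratum curves is the stated average", {
  mk_curve <- function(ppv, npv) {
    structure(data.frame(threshold = 1:3, n_test_pos = c(9, 6, 3),
                         n_test_neg = c(1, 4, 7),
                         ppv = ppv, ppv_low = ppv - 0.1, ppv_high = ppv + 0.1,
                         npv = npv, npv_low = npv - 0.1, npv_high = npv + 0.1),
              class = c("predictive_curve", "data.frame"))
  }
  cp <- mk_curve(rep(0.5, 3), rep(0.6, 3))
  cn <- mk_curve(rep(0.2, 3), rep(0.9, 3))
  w <- weight_curves(cp, cn, 0.06, 0.94)
  expect_equal(w$ppv, rep(0.06 * 0.5 + 0.94 * 0.2, 3))
  expect_equal(w$ppv[1], 0.218)
  # identical strata are invariant under any weights
  w2 <- weight_curves(cp, cp, 0.3, 0.7)
  expect_equal(w2$ppv, cp$ppv)
  expect_equal(w2$npv, cp$npv)
  # weight (1, 0) returns the FIT-positive curve
  w3 <- weight_curves(cp, cn, 1, 0)
  expect_equal(w3$ppv, cp$ppv)
  # weights (0.5, 0.5) equal the unweighted mean of stratum values
  w4 <- weight_curves(cp, cn, 0.5, 0.5)
  expect_equal(w4$npv, (cp$npv + cn$npv) / 2)
  # mismatched grids are an error
  cn2 <- mk_curve(rep(0.2, 3), rep(0.9, 3)); cn2$threshold <- 4:6
  expect_error(weight_curves(cp, cn2), "grids")
  # missing stratum values propagate
  cn3 <- mk_curve(c(0.2, NA, 0.2), rep(0.9, 3))
  expect_true(is.na(weight_curves(cp, cn3)$ppv[2]))
})
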