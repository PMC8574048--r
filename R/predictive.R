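#' Positive and negative predictive values at a score threshold
#'
#' Test-positive means `score >= threshold`. The PPV is the case fraction
#' among test-positives, the NPV the control fraction among test-negatives,
#' each with a Wilson score confidence interval. An empty test-positive
#' (or -negative) side leaves the corresponding value `NA`.
#'
#' @param scores Numeric scores.
#' @param labels Case indicators as in [roc_auc()].
#' @param threshold Decision threshold on the score scale.
#' @param conf.level Confidence level for the Wilson intervals.
#' @return One-row data frame: `threshold`, `n_test_pos`, `n_test_neg`,
#'   `ppv`, `ppv_low`, `ppv_high`, `npv`, `npv_low`, `npv_high`.
#' @export
predictive_values <- function(scores, labels, threshold, conf.level = 0.95) {
  labels <- as_case_labels(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  pos <- scores >= threshold
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos > 0) {
    x <- sum(labels[pos]); ppv <- x / n_pos
    ppv_ci <- wilson_ci(x, n_pos, conf.level)
  } else { ppv <- NA_real_; ppv_ci <- c(NA_real_, NA_real_) }
  if (n_neg > 0) {
    x <- sum(!labels[!pos]); npv <- x / n_neg
    npv_ci <- wilson_ci(x, n_neg, conf.level)
  } else { npv <- NA_real_; npv_ci <- c(NA_real_, NA_real_) }
  data.frame(threshold = threshold, n_test_pos = n_pos, n_test_neg = n_neg,
             ppv = ppv, ppv_low = ppv_ci[1], ppv_high = ppv_ci[2],
             npv = npv, npv_low = npv_ci[1], npv_high = npv_ci[2])
}

#' Predictive-value curve over a threshold grid
#'
#' Evaluates [predictive_values()] over an increasing grid of thresholds.
#' The default grid is the integer risk-allele counts spanning the observed
#' score range; percentile anchors (10th to 90th percentile of the analysis
#' sample, cases and controls combined) are recorded alongside.
#'
#' @param scores,labels As in [predictive_values()].
#' @param thresholds Increasing numeric grid; default integer counts
#'   spanning `range(scores)`.
#' @param stratum Label stored with the curve (e.g. `"all"`,
#'   `"fit_positive"`, `"fit_negative"`, `"population_weighted"`).
#' @return A `predictive_curve` data frame (one row per threshold, columns
#'   as in [predictive_values()]) with attributes `stratum` and
#'   `percentile_anchors` (named score values at p10..p90).
#' @export
predictive_curve <- function(scores, labels, thresholds = NULL,
                             stratum = "all") {
  if (is.null(thresholds))
    thresholds <- seq(floor(min(scores)), ceiling(max(scores)))
  if (!length(thresholds)) stopf("empty threshold grid")
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly increasing")
  rows <- lapply(thresholds, function(th)
    predictive_values(scores, labels, th))
  out <- do.call(rbind, rows)
  attr(out, "stratum") <- stratum
  attr(out, "percentile_anchors") <-
    quantile(scores, probs = seq(0.1, 0.9, by = 0.1), names = TRUE)
  class(out) <- c("predictive_curve", "data.frame")
  out
}

#' Population-weighted predictive-value curve across FIT strata
#'
#' Combines the FIT-positive and FIT-negative predictive-value curves into
#' a population estimate by a weighted average per threshold,
#' `w_pos * value_pos + w_neg * value_neg`. The default weights 0.06 / 0.94
#' are the approximate fractions of FIT-positive and FIT-negative results in
#' a population screening round, undoing the oversampling of FIT-positives
#' in the analysis cohort. A count-reweighting alternative (weighted counts
#' pooled before taking ratios) is available via `method = "counts"`.
#'
#' @param curve_fit_pos,curve_fit_neg [predictive_curve()]s on the same
#'   threshold grid.
#' @param w_pos,w_neg Stratum weights, summing to 1.
#' @param method `"average"` (the weighted average of stratum values, the
#'   primary estimator) or `"counts"`.
#' @return A `predictive_curve` with stratum `"population_weighted"`; a
#'   missing stratum value at a threshold propagates as `NA`.
#' @export
weight_curves <- function(curve_fit_pos, curve_fit_neg,
                          w_pos = 0.06, w_neg = 0.94,
                          method = c("average", "counts")) {
  method <- match.arg(method)
  if (abs(w_pos + w_neg - 1) > 1e-8) stopf("weights must sum to 1")
  if (!isTRUE(all.equal(curve_fit_pos$threshold, curve_fit_neg$threshold)))
    stopf("curves are on different threshold grids")
  out <- data.frame(threshold = curve_fit_pos$threshold)
  if (method == "average") {
    for (col in c("ppv", "npv")) {
      out[[col]] <- w_pos * curve_fit_pos[[col]] + w_neg * curve_fit_neg[[col]]
      out[[paste0(col, "_low")]] <- w_pos * curve_fit_pos[[paste0(col, "_low")]] +
        w_neg * curve_fit_neg[[paste0(col, "_low")]]
      out[[paste0(col, "_high")]] <- w_pos * curve_fit_pos[[paste0(col, "_high")]] +
        w_neg * curve_fit_neg[[paste0(col, "_high")]]
    }
  } else {
    # reweight stratum counts to population composition, then take ratios
    f_pos <- w_pos / sum(curve_fit_pos$n_test_pos[1] + curve_fit_pos$n_test_neg[1])
    f_neg <- w_neg / sum(curve_fit_neg$n_test_pos[1] + curve_fit_neg$n_test_neg[1])
    case_pos <- curve_fit_pos$ppv * curve_fit_pos$n_test_pos
    case_neg <- curve_fit_neg$ppv * curve_fit_neg$n_test_pos
    ctrl_pos <- curve_fit_pos$npv * curve_fit_pos$n_test_neg
    ctrl_neg <- curve_fit_neg$npv * curve_fit_neg$n_test_neg
    num_p <- f_pos * case_pos + f_neg * case_neg
    den_p <- f_pos * curve_fit_pos$n_test_pos + f_neg * curve_fit_neg$n_test_pos
    num_n <- f_pos * ctrl_pos + f_neg * ctrl_neg
    den_n <- f_pos * curve_fit_pos$n_test_neg + f_neg * curve_fit_neg$n_test_neg
    out$ppv <- ifelse(den_p > 0, num_p / den_p, NA_real_)
    out$npv <- ifelse(den_n > 0, num_n / den_n, NA_real_)
    out$ppv_low <- out$ppv_high <- out$npv_low <- out$npv_high <- NA_real_
  }
  attr(out, "stratum") <- "population_weighted"
  attr(out, "weights") <- c(w_pos = w_pos, w_neg = w_neg)
  class(out) <- c("predictive_curve", "data.frame")
  out
}
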