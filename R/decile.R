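#' Decile odds ratios relative to the bottom control-based decile
#'
#' Decile cut points are the empirical deciles of the score distribution in
#' the control group; bins are left-closed and right-open with the top bin
#' closed, so a sample lying exactly on a cut point goes to the upper bin.
#' Case status is regressed on the decile indicators (plus optional
#' covariates) by unconditional logistic regression with decile 1 as the
#' reference; Wald confidence intervals are reported, together with a
#' Mann-Kendall trend p-value across the ten odds-ratio estimates.
#'
#' @param scores Numeric scores (typically the adjusted PRS).
#' @param labels Case indicators as in [roc_auc()].
#' @param covariates Optional data frame of additional model covariates.
#' @param conf.level Confidence level of the Wald intervals.
#' @return A `decile_or_table` list: `table` (data frame with `decile`,
#'   `n_control`, `n_case`, `or`, `or_low`, `or_high`), `cut_points`
#'   (the 9 interior control deciles) and `trend_p`.
#' @export
decile_or <- function(scores, labels, covariates = NULL, conf.level = 0.95) {
  labels <- as_case_labels(labels)
  if (sum(!labels) < 10) stopf("need at least 10 controls to form deciles")
  cuts <- quantile(scores[!labels], probs = seq(0.1, 0.9, by = 0.1),
                   names = FALSE)
  decile <- findInterval(scores, cuts) + 1L  # score == cut -> upper bin
  decile <- factor(decile, levels = 1:10)
  counts_ctrl <- as.integer(table(decile[!labels]))
  counts_case <- as.integer(table(decile[labels]))

  df <- data.frame(y = labels, decile = decile)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- glm(y ~ ., data = df, family = binomial())
  cf <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf.level) / 2)
  or <- or_low <- or_high <- rep(NA_real_, 10)
  or[1] <- 1
  for (k in 2:10) {
    nm <- paste0("decile", k)
    if (nm %in% rownames(cf)) {
      b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
      or[k] <- exp(b); or_low[k] <- exp(b - z * se); or_high[k] <- exp(b + z * se)
    }
  }
  empty_case <- which(counts_case == 0)
  or[empty_case[empty_case > 1]] <- NA_real_
  trend_p <- if (all(is.finite(or))) mann_kendall_test(or)$p else NA_real_
  structure(list(
    table = data.frame(decile = 1:10, n_control = counts_ctrl,
                       n_case = counts_case, or = or,
                       or_low = or_low, or_high = or_high),
    cut_points = cuts, trend_p = trend_p,
    flagged_empty = empty_case), class = "decile_or_table")
}

#' @export
print.decile_or_table <- function(x, ...) {
  cat(sprintf("decile OR table (trend p = %.3g); OR D10 vs D1 = %.2f (%.2f-%.2f)\n",
              x$trend_p, x$table$or[10], x$table$or_low[10], x$table$or_high[10]))
  print(x$table, row.names = FALSE)
  invisible(x)
}
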