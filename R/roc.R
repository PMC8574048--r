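#' ROC curve and AUC with DeLong confidence interval
#'
#' The area under the ROC curve is the Mann-Whitney concordance probability
#' (ties count one half); the confidence interval uses the DeLong
#' placement-value variance with a normal interval truncated to \[0, 1\].
#' Computation is delegated to \pkg{pROC}, the standard implementation for
#' this statistic, oriented so that higher scores predict case status.
#'
#' @param scores Numeric predictor values.
#' @param labels Case indicators: logical, or 0/1 numeric (`TRUE`/1 = case).
#' @param ci Compute the DeLong confidence interval (default `TRUE`; skip
#'   for very large inputs where only the point estimate is needed).
#' @param conf.level Confidence level for the interval.
#' @return A `roc_result` list with `auc`, `ci_low`, `ci_high`, `n_case`,
#'   `n_control` and `curve` (a data frame of `fpr`, `tpr` anchored at
#'   (0,0) and (1,1)).
#' @export
roc_auc <- function(scores, labels, ci = TRUE, conf.level = 0.95) {
  labels <- as_case_labels(labels)
  if (!any(labels) || all(labels)) stopf("both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  if (ci) {
    ci_ <- as.numeric(pROC::ci.auc(r, method = "delong",
                                   conf.level = conf.level))
    ci_low <- max(0, ci_[1]); ci_high <- min(1, ci_[3])
  } else ci_low <- ci_high <- NA_real_
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 n_case = sum(labels), n_control = sum(!labels),
                 curve = curve, cv_folds = NULL, seed = NULL),
            class = "roc_result")
}

as_case_labels <- function(labels) {
  if (inherits(labels, "outcome_grouping")) return(labels$label)
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.factor(labels) && nlevels(labels) == 2)
    return(labels == levels(labels)[2])
  stopf("labels must be logical, 0/1, or a two-level factor")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), %d cases / %d controls%s\n",
              x$auc, x$ci_low, x$ci_high, x$n_case, x$n_control,
              if (!is.null(x$cv_folds))
                sprintf(" [%d-fold CV, seed %s]", x$cv_folds, x$seed) else ""))
  invisible(x)
}

#' DeLong test comparing two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two score vectors measured on
#' the same samples, using the DeLong placement-value covariance (as in
#' \pkg{pROC}'s `roc.test`). A degenerate comparison (identical placements,
#' e.g. a score against a monotone transform of itself) has AUC difference
#' zero and returns p = 1.
#'
#' @param scores_1,scores_2 Numeric score vectors on the same samples.
#' @param labels Case indicators as in [roc_auc()].
#' @return List with `auc_1`, `auc_2`, `statistic`, `p`.
#' @export
delong_paired_test <- function(scores_1, scores_2, labels) {
  labels <- as_case_labels(labels)
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels))
    stopf("score vectors and labels must have equal length")
  r1 <- pROC::roc(labels, as.numeric(scores_1), levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  r2 <- pROC::roc(labels, as.numeric(scores_2), levels = c(FALSE, TRUE),
                  direction = "<", quiet = TRUE)
  auc1 <- as.numeric(pROC::auc(r1)); auc2 <- as.numeric(pROC::auc(r2))
  tst <- suppressWarnings(
    try(pROC::roc.test(r1, r2, method = "delong", paired = TRUE),
        silent = TRUE))
  if (inherits(tst, "try-error") || is.nan(tst$p.value)) {
    if (abs(auc1 - auc2) < 1e-12)
      return(list(auc_1 = auc1, auc_2 = auc2, statistic = 0, p = 1))
    stopf("DeLong variance degenerate with unequal AUCs")
  }
  list(auc_1 = auc1, auc_2 = auc2,
       statistic = unname(tst$statistic), p = tst$p.value)
}

#' Cross-validated AUC of a logistic model
#'
#' Splits the samples into stratified folds (cases and controls allocated
#' separately, so every fold contains both classes), fits a logistic
#' regression of the label on the predictors in each training split, pools
#' the out-of-fold predicted probabilities into a single vector, and
#' computes one ROC/AUC on the pooled predictions. Pooling (rather than
#' averaging per-fold AUCs) is the stabler choice at cohort sizes around a
#' thousand or two.
#'
#' @param predictors Numeric vector, matrix or data frame of predictor
#'   columns.
#' @param labels Case indicators as in [roc_auc()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment (recorded in the result).
#' @return A `roc_result` (see [roc_auc()]) with `cv_folds`, `seed` and a
#'   `fold_hash` attribute identifying the fold assignment.
#' @export
cv_auc <- function(predictors, labels, folds = 5, seed = 1L) {
  labels <- as_case_labels(labels)
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(labels)
  if (nrow(X) != n) stopf("predictors and labels must have equal length")
  if (folds < 2) stopf("need at least 2 folds")
  if (sum(labels) < folds || sum(!labels) < folds)
    stopf("too few cases or controls for %d stratified folds; reduce folds",
          folds)
  fold <- integer(n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  fold[labels] <- sample(rep_len(seq_len(folds), sum(labels)))
  fold[!labels] <- sample(rep_len(seq_len(folds), sum(!labels)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  pred <- numeric(n)
  df <- data.frame(y = labels, X)
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- glm(y ~ ., data = df[!test, , drop = FALSE], family = binomial())
    pred[test] <- predict(fit, newdata = df[test, , drop = FALSE],
                          type = "response")
  }
  out <- roc_auc(pred, labels)
  out$cv_folds <- folds
  out$seed <- seed
  attr(out, "fold_hash") <- object_hash(fold)
  out
}

#' Closed-form AUC of the binormal model
#'
#' For normally distributed scores with case mean `mean_case`, control mean
#' `mean_control` and common (or per-group) standard deviations, the AUC is
#' `pnorm((mean_case - mean_control) / sqrt(sd_case^2 + sd_control^2))`.
#'
#' @param mean_case,mean_control Group means.
#' @param sd_case,sd_control Group standard deviations (`sd_control`
#'   defaults to `sd_case`).
#' @return The AUC.
#' @export
binormal_auc <- function(mean_case, mean_control, sd_case,
                         sd_control = sd_case) {
  pnorm((mean_case - mean_control) / sqrt(sd_case^2 + sd_control^2))
}
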