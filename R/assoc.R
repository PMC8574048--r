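#' Per-variant logistic association scan
#'
#' Fits, for every panel variant, an unconditional logistic regression of
#' case status on the effect-allele dosage (additive coding) plus any
#' supplied covariates, and reports the per-allele odds ratio with a Wald
#' confidence interval and p-value. Missing dosages are mean-imputed within
#' the analysis sample. Quasi-separated fits (huge or unstable estimates)
#' are flagged rather than silently reported.
#'
#' @param geno A [genotype_matrix()].
#' @param labels Case indicators as in [roc_auc()] (length = samples).
#' @param covariates Optional data frame / matrix of covariates (numeric
#'   columns or factors), one row per sample.
#' @param conf.level Confidence level of the Wald intervals.
#' @return Data frame with `variant_id`, `beta`, `se`, `or`, `or_low`,
#'   `or_high`, `p`, `separation` (logical flag).
#' @export
per_snp_logistic <- function(geno, labels, covariates = NULL,
                             conf.level = 0.95) {
  labels <- as_case_labels(labels)
  G <- unclass(geno)
  if (nrow(G) != length(labels)) stopf("labels must match genotype rows")
  Z <- matrix(1, nrow(G), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    mm <- model.matrix(~ ., data = as.data.frame(covariates))
    Z <- mm  # includes intercept
  }
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  y <- as.numeric(labels)
  res <- lapply(seq_len(ncol(G)), function(j) {
    d <- G[, j]
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    X <- cbind(Z, dosage = d)
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(), control = list(maxit = 50)))
    # Wald SE from the unscaled covariance of the final IRLS iteration,
    # honouring the QR pivot as summary.glm does
    k <- ncol(X)
    p1 <- seq_len(fit$rank)
    cov_u <- try(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]), silent = TRUE)
    idx <- match(k, fit$qr$pivot[p1])
    if (inherits(cov_u, "try-error") || !fit$converged || is.na(idx)) {
      return(data.frame(beta = NA_real_, se = NA_real_, or = NA_real_,
                        or_low = NA_real_, or_high = NA_real_, p = NA_real_,
                        separation = TRUE))
    }
    b <- fit$coefficients[k]
    se <- sqrt(cov_u[idx, idx])
    sep <- !is.finite(b) || abs(b) > 10 || se > 10
    data.frame(beta = b, se = se, or = exp(b),
               or_low = exp(b - zcrit * se), or_high = exp(b + zcrit * se),
               p = 2 * pnorm(-abs(b / se)), separation = sep)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(variant_id = colnames(G), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
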