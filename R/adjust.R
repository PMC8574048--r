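#' Covariate-adjust the polygenic risk score
#'
#' Regresses the unweighted PRS on sex, age, the leading ancestry principal
#' components, genotyping array and family history by ordinary least
#' squares, and returns the residuals re-centered at the grand mean of the
#' PRS. Re-adding the grand mean keeps the adjusted score on the
#' interpretable risk-allele-count scale (group means around 130 alleles for
#' a 133-variant panel) instead of centering at zero. Factors with a single
#' observed level are dropped with a warning; unknown family history is kept
#' as its own level rather than discarded.
#'
#' @param scores A [compute_scores()] result (or data frame with `sample_id`
#'   and `prs`).
#' @param cohort A [cohort_table()] (or data frame) with `sample_id`, `sex`,
#'   `age`, `array`, `family_history`.
#' @param pcs A [genotype_pca()] result or matrix of PC coordinates with
#'   sample ids as rownames; the first `n_pcs` columns are used.
#' @param n_pcs Number of ancestry components to adjust for (default 5).
#' @return An `adjusted_score_set` data frame with `sample_id`,
#'   `adjusted_prs` and, as attributes, the fitted `coefficients` and the
#'   `grand_mean`.
#' @export
adjust_prs <- function(scores, cohort, pcs = NULL, n_pcs = 5) {
  df <- merge(as.data.frame(scores)[, c("sample_id", "prs")],
              as.data.frame(cohort), by = "sample_id", sort = FALSE)
  if (nrow(df) != nrow(scores))
    warnf("%d scored sample(s) lack cohort covariates and were dropped",
          nrow(scores) - nrow(df))
  if (!is.null(pcs)) {
    coords <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
    n_pcs <- min(n_pcs, ncol(coords))
    pc_df <- data.frame(sample_id = rownames(coords),
                        coords[, seq_len(n_pcs), drop = FALSE],
                        stringsAsFactors = FALSE)
    df <- merge(df, pc_df, by = "sample_id", sort = FALSE)
  }
  terms <- c("sex", "age", "array", "family_history",
             if (!is.null(pcs)) paste0("PC", seq_len(n_pcs)))
  terms <- intersect(terms, names(df))
  # drop single-level factors (rank deficiency) with a warning
  keep <- vapply(terms, function(t) {
    v <- df[[t]]
    if (is.numeric(v)) TRUE else length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  if (any(!keep))
    warnf("dropping constant covariate(s): %s",
          paste(terms[!keep], collapse = ", "))
  terms <- terms[keep]
  for (t in terms)
    if (!is.numeric(df[[t]])) df[[t]] <- factor(df[[t]])
  grand_mean <- mean(df$prs)
  if (length(terms)) {
    fml <- stats::as.formula(paste("prs ~", paste(terms, collapse = " + ")))
    fit <- lm(fml, data = df)
    adj <- resid(fit) + grand_mean
    coefs <- coef(fit)
  } else {
    adj <- df$prs  # intercept-only: residual + mean = original values
    coefs <- c(`(Intercept)` = grand_mean)
  }
  out <- data.frame(sample_id = df$sample_id, adjusted_prs = as.numeric(adj),
                    stringsAsFactors = FALSE)
  attr(out, "coefficients") <- coefs
  attr(out, "grand_mean") <- grand_mean
  class(out) <- c("adjusted_score_set", "data.frame")
  out
}
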