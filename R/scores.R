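#' Compute unweighted and weighted polygenic risk scores
#'
#' The unweighted PRS of a sample is the sum of its effect-allele dosages
#' over the panel (a risk-allele count in \[0, 2m\] for m variants); the
#' weighted PRS is the weight-multiplied sum on the log-odds scale. Missing
#' dosages are mean-imputed as twice the panel risk-allele frequency, the
#' standard convention for score files, so every sample remains scorable
#' with an unbiased expectation; the number of imputed entries is recorded
#' per sample in `n_missing`.
#'
#' @param geno A [genotype_matrix()] aligned to `panel` (same column order).
#' @param panel A [snp_panel()].
#' @param use_hard_calls If `TRUE`, round dosages to hard calls (ties to
#'   even) before scoring; default `FALSE` scores the dosages as stored.
#' @return A `score_set` data frame with columns `sample_id`, `prs`, `wprs`,
#'   `n_variants_used`, `n_missing`.
#' @export
compute_scores <- function(geno, panel, use_hard_calls = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(panel, "snp_panel"))
  if (!identical(colnames(geno), panel$variant_id))
    stopf("genotype columns are not aligned to the panel")
  d <- unclass(geno)
  if (use_hard_calls) d <- hard_calls(d)
  miss <- is.na(d)
  if (any(miss)) {
    fill <- matrix(2 * panel$risk_allele_freq, nrow(d), ncol(d), byrow = TRUE)
    d[miss] <- fill[miss]
  }
  out <- data.frame(
    sample_id = rownames(geno),
    prs = as.numeric(d %*% rep(1, ncol(d))),
    wprs = as.numeric(d %*% panel$weight),
    n_variants_used = ncol(d) - rowSums(miss),
    n_missing = rowSums(miss),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_set", "data.frame")
  out
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("PRS for %d samples: mean %.1f (SD %.1f), range %.0f-%.0f\n",
              nrow(x), mean(x$prs), sd(x$prs), min(x$prs), max(x$prs)))
  invisible(x)
}
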