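#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the observed genotype counts
#' against the proportions p^2, 2pq, q^2 expected under Hardy-Weinberg
#' equilibrium, with the allele frequency estimated from the same counts.
#' A monomorphic site (allele frequency 0 or 1) fits HWE trivially and
#' returns p = 1.
#'
#' @param n_hom_effect Count of effect-allele homozygotes (dosage 2).
#' @param n_het Count of heterozygotes (dosage 1).
#' @param n_hom_other Count of other-allele homozygotes (dosage 0).
#' @return List with `chisq`, `p`, and the estimated allele frequency `p_hat`.
#' @export
hwe_test <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(counts < 0)) stopf("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stopf("no genotypes to test")
  p_hat <- (2 * n_hom_effect + n_het) / (2 * n)
  if (p_hat == 0 || p_hat == 1)
    return(list(chisq = 0, p = 1, p_hat = p_hat))
  expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       p_hat = p_hat)
}

#' Default variant/sample QC thresholds
#'
#' Variants are excluded when the HWE test p-value falls below `hwe_p`, the
#' observed minor allele frequency below `maf`, the missing fraction above
#' `missing`, or the panel imputation info score below `info`. Samples are
#' excluded when their missing fraction exceeds `sample_missing`.
#'
#' @param hwe_p,maf,missing,info,sample_missing Numeric thresholds.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(hwe_p = 1e-4, maf = 0.001, missing = 0.05,
                          info = 0.3, sample_missing = 0.01) {
  list(hwe_p = hwe_p, maf = maf, missing = missing, info = info,
       sample_missing = sample_missing)
}

# Hard calls from dosage: nearest integer, ties to even (base round()).
hard_calls <- function(dosage) round(dosage)

#' Variant-level quality control
#'
#' Applies, in order, the missingness, minor-allele-frequency, HWE and
#' imputation-info filters. HWE is evaluated on hard-called genotypes
#' (dosage rounded to the nearest integer, ties to even) across all samples;
#' MAF and missingness on the observed dosages; the info filter on the panel
#' metadata (variants without an info score are not filtered on it).
#'
#' @param geno A [genotype_matrix()] aligned to `panel`.
#' @param panel A [snp_panel()].
#' @param thresholds See [qc_thresholds()].
#' @param hwe_samples Optional character vector of sample ids on which to
#'   evaluate the HWE test (e.g. controls only); default all samples.
#' @return List with `geno` (passing variants only), `panel` (subset to the
#'   same variants) and `report`, a per-variant data frame with the computed
#'   statistics, `pass` flag and failure `reason` (`"missingness"`, `"maf"`,
#'   `"hwe"`, `"info"`, or several joined by `"+"`).
#' @export
qc_variants <- function(geno, panel, thresholds = qc_thresholds(),
                        hwe_samples = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(panel, "snp_panel"))
  if (!identical(colnames(geno), panel$variant_id))
    stopf("genotype columns are not aligned to the panel")
  hwe_rows <- if (is.null(hwe_samples)) seq_len(nrow(geno))
              else which(rownames(geno) %in% hwe_samples)
  if (!length(hwe_rows)) stopf("hwe_samples matches no genotyped sample")
  miss <- colMeans(is.na(geno))
  eaf <- colMeans(geno, na.rm = TRUE) / 2
  eaf[is.nan(eaf)] <- NA_real_
  maf <- pmin(eaf, 1 - eaf)
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    hc <- hard_calls(geno[hwe_rows, j])
    hc <- hc[!is.na(hc)]
    if (!length(hc)) return(NA_real_)
    hwe_test(sum(hc == 2), sum(hc == 1), sum(hc == 0))$p
  }, numeric(1))

  fail_missing <- miss > thresholds$missing
  fail_maf <- !is.na(maf) & maf < thresholds$maf
  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p
  fail_info <- !is.na(panel$info_score) & panel$info_score < thresholds$info
  # an all-missing variant has no MAF/HWE; it fails on missingness alone
  fail_maf[is.na(maf)] <- FALSE

  reasons <- cbind(missingness = fail_missing, maf = fail_maf,
                   hwe = fail_hwe, info = fail_info)
  reason <- apply(reasons, 1, function(r)
    if (any(r)) paste(colnames(reasons)[r], collapse = "+") else "")
  pass <- reason == ""

  report <- data.frame(
    variant_id = panel$variant_id,
    hwe_p = hwe_p, maf = maf, missing_frac = miss,
    info_score = panel$info_score,
    pass = pass, reason = reason,
    stringsAsFactors = FALSE
  )
  if (!any(pass)) stopf("no variant survives QC")
  keep <- which(pass)
  out_panel <- panel[keep, , drop = FALSE]
  class(out_panel) <- class(panel)
  list(geno = genotype_matrix(geno[, keep, drop = FALSE]),
       panel = out_panel, report = report)
}

#' Sample-level quality control on missingness
#'
#' @param geno A [genotype_matrix()].
#' @param threshold Maximum tolerated missing fraction (strictly greater
#'   fails); default 0.01.
#' @return List with `geno` (passing samples) and `report` (per-sample
#'   missing fraction, `pass`, `reason`).
#' @export
qc_samples <- function(geno, threshold = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  miss <- rowMeans(is.na(geno))
  pass <- miss <= threshold
  report <- data.frame(sample_id = rownames(geno), missing_frac = miss,
                       pass = pass,
                       reason = ifelse(pass, "", "missingness"),
                       stringsAsFactors = FALSE)
  if (!any(pass)) stopf("no sample survives QC")
  list(geno = genotype_matrix(geno[pass, , drop = FALSE]), report = report)
}
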