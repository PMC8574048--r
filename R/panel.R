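#' Construct a SNP score panel
#'
#' A panel is the set of independent variants that defines the polygenic
#' risk score: one row per variant with its effect (risk) allele, the other
#' allele, the per-allele log-odds weight, the risk-allele frequency, and an
#' optional imputation quality (info/R-squared) score.
#'
#' @param variant_id Character, unique variant identifiers (e.g. rs ids).
#' @param chromosome Character or integer chromosome labels.
#' @param position 1-based integer coordinates.
#' @param effect_allele,other_allele Allele strings; must differ per variant.
#' @param weight Per-allele log-odds weights; must be finite.
#' @param risk_allele_freq Risk-allele frequencies, strictly inside (0, 1).
#' @param info_score Optional imputation quality in \[0, 1\]; `NA` allowed.
#' @return An object of class `snp_panel` (a data frame).
#' @export
snp_panel <- function(variant_id, chromosome, position, effect_allele,
                      other_allele, weight, risk_allele_freq,
                      info_score = NULL) {
  variant_id <- as.character(variant_id)
  if (anyDuplicated(variant_id))
    stopf("duplicate variant ids in panel: %s",
          paste(unique(variant_id[duplicated(variant_id)]), collapse = ", "))
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  if (any(effect_allele == other_allele))
    stopf("effect allele equals other allele for: %s",
          paste(variant_id[effect_allele == other_allele], collapse = ", "))
  weight <- as.numeric(weight)
  if (any(!is.finite(weight)))
    stopf("non-finite weights for: %s",
          paste(variant_id[!is.finite(weight)], collapse = ", "))
  risk_allele_freq <- as.numeric(risk_allele_freq)
  if (any(is.na(risk_allele_freq)) ||
      any(risk_allele_freq <= 0 | risk_allele_freq >= 1))
    stopf("risk allele frequencies must lie strictly inside (0, 1)")
  if (is.null(info_score)) info_score <- rep(NA_real_, length(variant_id))
  info_score <- as.numeric(info_score)
  if (any(!is.na(info_score) & (info_score < 0 | info_score > 1)))
    stopf("info scores must lie in [0, 1]")
  amb <- is_strand_ambiguous(effect_allele, other_allele)
  if (any(amb))
    warnf("%d strand-ambiguous (A/T or C/G) variant(s) in panel; trusting the stated orientation",
          sum(amb))
  out <- data.frame(
    variant_id = variant_id,
    chromosome = as.character(chromosome),
    position = as.integer(position),
    effect_allele = effect_allele,
    other_allele = other_allele,
    weight = weight,
    risk_allele_freq = risk_allele_freq,
    info_score = info_score,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Read a SNP score panel from a delimited file
#'
#' The file must be tab- (or comma-) delimited with a header naming at least
#' `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `weight` and `risk_allele_freq`; an `info_score` column is optional.
#'
#' @param path Path to the panel file.
#' @param sep Field separator (default tab).
#' @return A [snp_panel()] object.
#' @export
read_panel <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  required <- c("variant_id", "chromosome", "position", "effect_allele",
                "other_allele", "weight", "risk_allele_freq")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("panel file %s lacks required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  snp_panel(df$variant_id, df$chromosome, df$position, df$effect_allele,
            df$other_allele, df$weight, df$risk_allele_freq,
            info_score = if ("info_score" %in% names(df)) df$info_score)
}

#' Write a panel back to a TSV file
#' @param panel A [snp_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d variants, weights in [%.3g, %.3g]\n",
              nrow(x), min(x$weight), max(x$weight)))
  NextMethod()
}
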