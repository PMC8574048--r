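# Small builders shared across the test files. Everything is generated in
# code; no binary fixtures.

toy_panel <- function(m = 3, weights = seq(0.1, by = 0.1, length.out = m),
                      raf = rep(0.3, m)) {
  snp_panel(variant_id = paste0("v", seq_len(m)),
            chromosome = rep("1", m),
            position = seq_len(m) * 100,
            effect_allele = rep("A", m),
            other_allele = rep("G", m),
            weight = weights,
            risk_allele_freq = raf)
}

toy_geno <- function(dosage, panel) {
  dosage <- as.matrix(dosage)
  dimnames(dosage) <- list(paste0("s", seq_len(nrow(dosage))),
                           panel$variant_id)
  genotype_matrix(dosage)
}

write_panel_file <- function(panel, path = tempfile(fileext = ".tsv")) {
  write_panel(panel, path)
}

# Minimal VCF writer for reader tests (GT or GT:DS records).
write_toy_vcf <- function(records, samples,
                          path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# Cohort table expanded from the bundled reference FIT-stratified counts,
# with population controls and clinically diagnosed cancers appended.
reference_cohort <- function(with_nonscreening = FALSE) {
  counts <- reference_screening_fit_counts()
  ch <- cohort_from_counts(counts)
  if (with_nonscreening) {
    extra <- cohort_table(
      sample_id = sprintf("X%05d", 1:2015),
      sex = "male", age = 64, array = "array_A", family_history = "no",
      fit_result = "not_tested",
      risk_group = rep(c("population_control", "clinical_CRC"),
                       c(1008, 1007)))
    ch <- rbind(ch, extra)
    class(ch) <- c("cohort_table", "data.frame")
  }
  ch
}

# Brute-force AUC oracle: all-pairs concordance with ties counting one half.
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels]
  ct <- scores[!labels]
  mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
}
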