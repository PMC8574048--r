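#' Construct a genotype dosage matrix
#'
#' Dosages count copies of the panel effect allele per sample and variant,
#' as real numbers in \[0, 2\] (imputed dosages allowed); `NA` marks missing.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns, with
#'   `rownames` = sample ids and `colnames` = variant ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stopf("dosage matrix needs sample ids as rownames and variant ids as colnames")
  bad <- !is.na(dosage) & (dosage < 0 | dosage > 2)
  if (any(bad))
    stopf("%d dosage value(s) outside [0, 2]", sum(bad))
  structure(dosage, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d samples x %d variants, %.2f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read genotypes and orient them to a panel's effect alleles
#'
#' Accepts a VCF (`.vcf` / `.vcf.gz`; `DS` dosage field preferred, `GT`
#' used otherwise) or a plain tab-delimited dosage table (first column
#' `sample_id`, remaining columns named by variant id, values = effect-allele
#' dosage). VCF records are matched to the panel by variant id, falling back
#' to chromosome+position; when the VCF ALT allele is the panel effect allele
#' the dosage is kept, when the REF allele is the effect allele it is flipped
#' to `2 - d`, and any other allele pair is an error. Panel variants absent
#' from the file come back as all-missing columns so that downstream
#' missingness accounting sees them.
#'
#' @param path Path to a VCF or dosage table.
#' @param panel A [snp_panel()].
#' @return A [genotype_matrix()] with columns in panel order.
#' @export
read_genotypes <- function(path, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path, panel)
  } else {
    read_genotypes_table(path, panel)
  }
}

read_genotypes_table <- function(path, panel) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!ncol(df) >= 2) stopf("dosage table %s has no variant columns", path)
  samples <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- samples
  out <- matrix(NA_real_, nrow(mat), nrow(panel),
                dimnames = list(samples, panel$variant_id))
  found <- intersect(panel$variant_id, colnames(mat))
  out[, found] <- mat[, found]
  genotype_matrix(out)
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  key_pos <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  panel_pos <- paste(panel$chromosome, panel$position, sep = ":")

  # dosage of the ALT allele per record
  fmt <- vcf@gt[, 1]
  has_ds <- any(grepl("\\bDS\\b", strsplit(fmt[1], ":")[[1]]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), count_alt_alleles)
  }
  samples <- colnames(ds)
  out <- matrix(NA_real_, length(samples), nrow(panel),
                dimnames = list(samples, panel$variant_id))

  for (j in seq_len(nrow(panel))) {
    i <- match(panel$variant_id[j], ids)
    if (is.na(i)) i <- match(panel_pos[j], key_pos)
    if (is.na(i)) next  # absent variant stays all-missing
    ref <- toupper(fix[i, "REF"]); alt <- toupper(fix[i, "ALT"])
    d <- ds[i, ]
    if (alt == panel$effect_allele[j] && ref == panel$other_allele[j]) {
      out[, j] <- d
    } else if (ref == panel$effect_allele[j] && alt == panel$other_allele[j]) {
      out[, j] <- 2 - d
    } else {
      stopf("variant %s: VCF alleles %s/%s match neither orientation of panel %s/%s",
            panel$variant_id[j], ref, alt,
            panel$effect_allele[j], panel$other_allele[j])
    }
  }
  genotype_matrix(out)
}

count_alt_alleles <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

#' Write a genotype matrix as a dosage TSV
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(sample_id = rownames(geno),
                   unclass(geno)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
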