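#' Reference summary statistics from a published FIT-based screening study
#'
#' Group-level summary statistics of the adjusted 133-SNP PRS reported for a
#' large colorectal screening cohort (seven ordered outcome groups from
#' population controls to clinically diagnosed CRC). These are aggregate
#' published values, shipped as inputs for examples, trend testing on group
#' means, and reproduction checks; no individual-level data are included.
#'
#' @return Data frame with `risk_group`, `n`, `mean_adjusted_prs`,
#'   `sd_adjusted_prs`, ordered along the tumorigenesis pathway.
#' @seealso [reference_screening_fit_counts()]
#' @export
reference_group_summary <- function() {
  df <- read.delim(system.file("extdata", "reference_group_summary.tsv",
                               package = "prscreen"),
                   stringsAsFactors = FALSE)
  df$risk_group <- factor(df$risk_group, levels = risk_group_levels(),
                          ordered = TRUE)
  df
}

#' Reference FIT-stratified counts of the screening subset
#'
#' Counts of FIT-negative and FIT-positive participants per screening
#' outcome group in the same reference study (1604 participants, 77%
#' FIT-positive), used to reconstruct outcome groupings and overall
#' predictive values from published margins.
#'
#' @return Data frame with `risk_group`, `fit_negative`, `fit_positive`.
#' @export
reference_screening_fit_counts <- function() {
  df <- read.delim(system.file("extdata",
                               "reference_screening_fit_counts.tsv",
                               package = "prscreen"),
                   stringsAsFactors = FALSE)
  df$risk_group <- factor(df$risk_group, levels = risk_group_levels(),
                          ordered = TRUE)
  df
}

#' Expand FIT-stratified counts into a per-sample cohort table
#'
#' Utility to turn group-by-FIT counts (as from
#' [reference_screening_fit_counts()]) into a minimal [cohort_table()] with
#' one row per participant, so that counting operations such as
#' [group_outcomes()] and overall predictive values can run on published
#' margins.
#'
#' @param counts Data frame with `risk_group` and count columns
#'   `fit_negative`, `fit_positive` (and optionally `not_tested`).
#' @return A [cohort_table()] with placeholder covariates.
#' @export
cohort_from_counts <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (fr in intersect(c("fit_negative", "fit_positive", "not_tested"),
                         names(counts))) {
      n <- counts[[fr]][i]
      if (is.na(n) || n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        risk_group = as.character(counts$risk_group[i]),
        fit_result = c(fit_negative = "negative", fit_positive = "positive",
                       not_tested = "not_tested")[[fr]],
        n = n, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  total <- sum(long$n)
  cohort_table(
    sample_id = sprintf("C%05d", seq_len(total)),
    sex = "female", age = 60, array = "array_A", family_history = "no",
    fit_result = rep(long$fit_result, long$n),
    risk_group = rep(long$risk_group, long$n)
  )
}
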