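#' Construct a cohort phenotype table
#'
#' One row per sample: demographics, genotyping batch, family history of
#' colorectal cancer, fecal immunochemical test (FIT) result, and the
#' ordered seven-level screening outcome group (see [risk_group_levels()]).
#' When a quantitative FIT value (ug Hb / g feces) is supplied, the binary
#' result must equal `positive` exactly when the value reaches the 20
#' ug Hb/g referral cutoff.
#'
#' @param sample_id Unique sample identifiers.
#' @param sex `"female"` / `"male"`.
#' @param age Age in years, positive.
#' @param array Genotyping array / batch label.
#' @param family_history `"yes"`, `"no"` or `"unknown"`.
#' @param fit_result `"positive"`, `"negative"` or `"not_tested"`.
#' @param risk_group One of [risk_group_levels()].
#' @param fit_value Optional quantitative FIT, ug Hb / g feces.
#' @param ancestry Optional ancestry label.
#' @return A `cohort_table` data frame; `risk_group` is an ordered factor.
#' @export
cohort_table <- function(sample_id, sex, age, array, family_history,
                         fit_result, risk_group, fit_value = NULL,
                         ancestry = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in cohort table")
  sex <- match_levels(sex, c("female", "male"), "sex")
  age <- as.numeric(age)
  if (any(is.na(age) | age <= 0)) stopf("ages must be positive")
  family_history <- match_levels(family_history, c("yes", "no", "unknown"),
                                 "family_history")
  fit_result <- match_levels(fit_result, c("positive", "negative", "not_tested"),
                             "fit_result")
  risk_group <- factor(as.character(risk_group), levels = risk_group_levels(),
                       ordered = TRUE)
  if (anyNA(risk_group)) stopf("unknown risk group label(s)")
  if (!is.null(fit_value)) {
    fit_value <- as.numeric(fit_value)
    tested <- !is.na(fit_value)
    implied <- ifelse(fit_value[tested] >= 20, "positive", "negative")
    if (any(fit_result[tested] != implied))
      stopf("fit_result inconsistent with fit_value at the 20 ug Hb/g cutoff")
  } else fit_value <- rep(NA_real_, length(sample_id))
  out <- data.frame(sample_id = sample_id, sex = sex, age = age,
                    array = as.character(array),
                    family_history = family_history,
                    fit_value = fit_value, fit_result = fit_result,
                    risk_group = risk_group,
                    ancestry = if (is.null(ancestry)) NA_character_
                               else as.character(ancestry),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !x %in% levels
  if (any(bad))
    stopf("invalid %s value(s): %s", what,
          paste(unique(x[bad]), collapse = ", "))
  x
}

#' Read a cohort phenotype table from TSV
#'
#' Required columns: `sample_id`, `sex`, `age`, `array`, `family_history`,
#' `fit_result`, `risk_group`; optional `fit_value`, `ancestry`.
#'
#' @param path Path to the TSV file.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "sex", "age", "array", "family_history",
                "fit_result", "risk_group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("cohort file %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  cohort_table(df$sample_id, df$sex, df$age, df$array, df$family_history,
               df$fit_result, df$risk_group,
               fit_value = df$fit_value, ancestry = df$ancestry)
}
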