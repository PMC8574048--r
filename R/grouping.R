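#' Dichotomize the seven-level outcome into cases and controls
#'
#' Three schemes are supported:
#' \describe{
#'   \item{`primary_screening`}{cases = IRL, HRL, screening CRC; controls =
#'     screening controls, LRL. Population controls and clinically diagnosed
#'     CRC are excluded (they are outside the screening programme).}
#'   \item{`highrisk_screening`}{cases = HRL, screening CRC; controls =
#'     screening controls, LRL, IRL (sensitivity definition).}
#'   \item{`overall`}{cases = IRL, HRL, screening CRC, clinical CRC;
#'     controls = population controls, screening controls, LRL.}
#' }
#'
#' @param cohort A [cohort_table()] (or data frame with `risk_group`).
#' @param scheme One of `"primary_screening"`, `"highrisk_screening"`,
#'   `"overall"`.
#' @return An `outcome_grouping` list with `scheme`, `label` (logical vector
#'   over the retained samples, `TRUE` = case), `sample_id`, `n_case`,
#'   `n_control` and the row `index` of retained samples in `cohort`.
#' @export
group_outcomes <- function(cohort, scheme = c("primary_screening",
                                              "highrisk_screening",
                                              "overall")) {
  scheme <- match.arg(scheme)
  if (!nrow(cohort)) stopf("empty cohort")
  rg <- as.character(cohort$risk_group)
  sets <- switch(scheme,
    primary_screening = list(case = c("IRL", "HRL", "screening_CRC"),
                             control = c("screening_control", "LRL")),
    highrisk_screening = list(case = c("HRL", "screening_CRC"),
                              control = c("screening_control", "LRL", "IRL")),
    overall = list(case = c("IRL", "HRL", "screening_CRC", "clinical_CRC"),
                   control = c("population_control", "screening_control", "LRL"))
  )
  idx <- which(rg %in% c(sets$case, sets$control))
  label <- rg[idx] %in% sets$case
  structure(list(scheme = scheme, label = label,
                 sample_id = cohort$sample_id[idx], index = idx,
                 n_case = sum(label), n_control = sum(!label)),
            class = "outcome_grouping")
}

#' @export
print.outcome_grouping <- function(x, ...) {
  cat(sprintf("%s: %d cases / %d controls\n", x$scheme, x$n_case, x$n_control))
  invisible(x)
}
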