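#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf.level Two-sided confidence level.
#' @return Numeric vector `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @keywords internal
wilson_ci <- function(x, n, conf.level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# Stable content hash used in run manifests: md5 of the serialized object.
object_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' The seven ordered screening outcome groups
#'
#' Ordered from the group expected to carry the least genetic liability to
#' the most: population controls, screening controls (normal colonoscopy),
#' low-, intermediate- and high-risk colorectal lesions, screen-detected
#' colorectal cancer, and clinically diagnosed colorectal cancer.
#'
#' @return Character vector of the seven level names, in order.
#' @export
risk_group_levels <- function() {
  c("population_control", "screening_control", "LRL", "IRL", "HRL",
    "screening_CRC", "clinical_CRC")
}

# Groups that belong to the FIT-based screening programme (receive a FIT and
# are eligible for the screening-subset analyses).
screening_levels <- function() risk_group_levels()[2:6]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
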