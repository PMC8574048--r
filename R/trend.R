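#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotone trend in an ordered sequence. The
#' statistic is the pair-concordance count `S = sum_{i<j} sign(x_j - x_i)`,
#' its variance uses the standard tie correction
#' `varS = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie groups of size
#' `t`, and the two-sided p-value comes from the normal approximation with
#' continuity correction, `z = (S - sign(S)) / sqrt(varS)`.
#'
#' @param values Numeric sequence in its natural order (n >= 3).
#' @return List with `S`, `varS`, `z`, `p`, `n`.
#' @export
mann_kendall_test <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stopf("Mann-Kendall needs at least 3 values")
  if (anyNA(values)) stopf("missing values not supported")
  S <- 0L
  for (i in seq_len(n - 1))
    S <- S + sum(sign(values[(i + 1):n] - values[i]))
  ties <- table(values)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (varS <= 0) return(list(S = S, varS = 0, z = 0, p = 1, n = n))
  z <- if (S == 0) 0 else (S - sign(S)) / sqrt(varS)
  list(S = as.integer(S), varS = varS, z = z,
       p = min(1, 2 * pnorm(-abs(z))), n = n)
}

#' Two-sample Student's t test with optional Bonferroni adjustment
#'
#' Pooled-variance two-sided t test; when `bonferroni_m` is given, the
#' p-value is multiplied by `m` and capped at 1. Degenerate inputs with zero
#' pooled variance return p = 1 when the group means agree and p = 0 (with a
#' `degenerate` flag) otherwise.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param bonferroni_m Optional number of comparisons.
#' @return List with `t`, `df`, `p`, `p_adjusted`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
t_test_groups <- function(values_a, values_b, bonferroni_m = NULL) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each group needs at least 2 observations")
  pooled_var <- ((length(values_a) - 1) * var(values_a) +
                   (length(values_b) - 1) * var(values_b)) /
    (length(values_a) + length(values_b) - 2)
  if (pooled_var == 0) {
    equal <- mean(values_a) == mean(values_b)
    p <- if (equal) 1 else 0
    res <- list(t = if (equal) 0 else Inf,
                df = length(values_a) + length(values_b) - 2,
                p = p, degenerate = TRUE)
  } else {
    tt <- t.test(values_a, values_b, var.equal = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE)
  }
  res$mean_a <- mean(values_a)
  res$mean_b <- mean(values_b)
  res$p_adjusted <- if (is.null(bonferroni_m)) res$p
                    else min(1, res$p * bonferroni_m)
  res
}
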