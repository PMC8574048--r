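#' Configuration of the synthetic screening-cohort generator
#'
#' The generator draws a panel of independent biallelic variants, genotypes
#' under Hardy-Weinberg equilibrium, a latent liability equal to the
#' centered weighted score plus Gaussian noise, ordered outcome categories
#' cut from the liability at the category prevalences, severity-dependent
#' FIT positivity, and a FIT-stratified screening sample in which all
#' FIT-positives but only a small fraction of FIT-negatives reach
#' colonoscopy. Defaults describe a population screening round: about 6.5%
#' of tested participants FIT-positive, a screening subset that is ~77%
#' FIT-positive, and per-category lesion prevalences whose FIT-positive mix
#' matches a FIT-triggered colonoscopy series (roughly 36% normal, 17%
#' low-risk, 25% intermediate-risk, 17% high-risk lesions and 6% cancer).
#'
#' @param m_variants Number of panel variants (default 133).
#' @param raf_range Risk-allele frequency range, uniform draw (default
#'   \[0.1, 0.9\]).
#' @param weight_range Range of per-allele log-odds magnitudes before
#'   scaling (default \[0.05, 0.2\], the order of published CRC GWAS
#'   effects).
#' @param effect_scale Multiplier on the drawn weights; `NULL` (default)
#'   calibrates it with [calibrate_effects()] to `target_auc`.
#' @param target_auc Case/control AUC the calibrated generator aims for
#'   (default 0.56).
#' @param liability_noise_sd SD of the non-genetic liability component
#'   (default 1, on the log-odds-like scale of the weighted score).
#' @param category_prevalences Named 7-vector of ordered category
#'   proportions over the simulated population, summing to 1.
#' @param fit_positive_prob Named 7-vector of FIT positivity probabilities;
#'   `NA` marks groups outside the screening programme (population controls,
#'   clinically diagnosed CRC), which are recorded as `not_tested`.
#' @param fitneg_retention Probability that a FIT-negative participant is
#'   sampled into the colonoscopy study (default 0.0207, tuned so the
#'   screening subset is ~77% FIT-positive at the default population size).
#' @param n_population Number of simulated individuals (default 24000,
#'   which yields a screening subset of about 1600).
#' @param prop_female Proportion of females (default 0.46).
#' @param batch_effect Dosage artifact, in risk alleles, added to samples on
#'   the second genotyping array (spread over variants and clipped to
#'   \[0, 2\]); default 0. Used to exercise covariate adjustment.
#' @param seed Integer seed; every downstream draw is derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_variants = 133,
                       raf_range = c(0.1, 0.9),
                       weight_range = c(0.05, 0.2),
                       effect_scale = NULL,
                       target_auc = 0.56,
                       liability_noise_sd = 1,
                       category_prevalences = c(
                         population_control = 0.200,
                         screening_control = 0.521,
                         LRL = 0.143, IRL = 0.085, HRL = 0.029,
                         screening_CRC = 0.003, clinical_CRC = 0.019),
                       fit_positive_prob = c(
                         population_control = NA, screening_control = 0.035,
                         LRL = 0.06, IRL = 0.15, HRL = 0.30,
                         screening_CRC = 0.985, clinical_CRC = NA),
                       fitneg_retention = 0.0207,
                       n_population = 24000,
                       prop_female = 0.46,
                       batch_effect = 0,
                       seed = 1L) {
  cfg <- list(m_variants = m_variants, raf_range = raf_range,
              weight_range = weight_range, effect_scale = effect_scale,
              target_auc = target_auc,
              liability_noise_sd = liability_noise_sd,
              category_prevalences = category_prevalences,
              fit_positive_prob = fit_positive_prob,
              fitneg_retention = fitneg_retention,
              n_population = n_population, prop_female = prop_female,
              batch_effect = batch_effect, seed = as.integer(seed))
  validate_sim_config(cfg)
  if (is.null(cfg$effect_scale))
    cfg$effect_scale <- calibrate_effects(cfg$target_auc, cfg)$effect_scale
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  lv <- risk_group_levels()
  prev <- cfg$category_prevalences
  if (length(prev) != 7 || is.null(names(prev)) || !setequal(names(prev), lv))
    stopf("category_prevalences must be named with the 7 risk groups")
  if (abs(sum(prev) - 1) > 1e-8) stopf("category prevalences must sum to 1")
  if (any(prev < 0)) stopf("category prevalences must be non-negative")
  fp <- cfg$fit_positive_prob
  if (length(fp) != 7 || !setequal(names(fp), lv))
    stopf("fit_positive_prob must be named with the 7 risk groups")
  if (any(!is.na(fp) & (fp < 0 | fp > 1)))
    stopf("FIT positivity probabilities must lie in [0, 1]")
  fps <- fp[screening_levels()]
  if (anyNA(fps)) stopf("screening groups need a FIT positivity probability")
  if (is.unsorted(fps)) stopf("FIT positivity must be non-decreasing in severity")
  if (any(cfg$raf_range <= 0) || any(cfg$raf_range >= 1) ||
      diff(cfg$raf_range) < 0)
    stopf("raf_range must be an interval inside (0, 1)")
  if (cfg$fitneg_retention <= 0 || cfg$fitneg_retention > 1)
    stopf("fitneg_retention must lie in (0, 1]")
  if (cfg$m_variants < 1) stopf("need at least one variant")
  invisible(cfg)
}

# Closed-form moments of the generator given the config.
sim_moments <- function(cfg) {
  a <- cfg$raf_range[1]; b <- cfg$raf_range[2]
  Ep <- (a + b) / 2
  Ep2 <- (a^2 + a * b + b^2) / 3
  E2pq <- 2 * (Ep - Ep2)
  w1 <- cfg$weight_range[1]; w2 <- cfg$weight_range[2]
  Eu <- (w1 + w2) / 2
  Eu2 <- (w1^2 + w1 * w2 + w2^2) / 3
  list(prs_mean = 2 * cfg$m_variants * Ep,
       prs_var = cfg$m_variants * E2pq,
       cov_prs_wprs_per_scale = cfg$m_variants * Eu * E2pq,
       wprs_var_per_scale2 = cfg$m_variants * Eu2 * E2pq)
}

# Expected standardized-liability mean per category (truncated normal slices
# at the category prevalences) and the expected screening-sample category mix.
sim_category_geometry <- function(cfg) {
  prev <- cfg$category_prevalences[risk_group_levels()]
  cum <- cumsum(prev)
  lo <- qnorm(c(0, cum[-7])); hi <- qnorm(cum)
  m_c <- ifelse(prev > 0, (dnorm(lo) - dnorm(hi)) / prev, NA_real_)
  names(m_c) <- names(prev)
  fp <- cfg$fit_positive_prob[risk_group_levels()]
  sl <- screening_levels()
  w <- prev[sl] * (fp[sl] + (1 - fp[sl]) * cfg$fitneg_retention)
  list(slice_mean = m_c, screening_weight = w)
}

#' Calibrate the generator's effect scale to a target AUC
#'
#' Chooses the multiplier on the per-allele weights so that the expected
#' case-control mean difference of the unweighted PRS (cases = IRL, HRL and
#' screening CRC, controls = screening controls and LRL, mixed according to
#' the FIT-stratified sampling design) satisfies the binormal identity
#' `AUC = pnorm(delta / (sigma * sqrt(2)))`, with `sigma` the PRS standard
#' deviation implied by the panel. The mapping uses closed-form
#' truncated-normal slice means of the liability, so it is deterministic
#' given the config.
#'
#' @param target_auc Target AUC, in (0.5, 1).
#' @param config A [sim_config()] (its `effect_scale` entry is ignored).
#' @return List with `effect_scale`, `predicted_delta` (expected
#'   case-control PRS gap, in risk alleles) and `prs_sd`.
#' @export
calibrate_effects <- function(target_auc, config) {
  if (target_auc == 0.5)
    return(list(effect_scale = 0, predicted_delta = 0,
                prs_sd = sqrt(sim_moments(config)$prs_var)))
  if (target_auc <= 0.5 || target_auc >= 1)
    stopf("target AUC must lie in [0.5, 1)")
  mom <- sim_moments(config)
  geo <- sim_category_geometry(config)
  w <- geo$screening_weight
  cases <- c("IRL", "HRL", "screening_CRC")
  ctrls <- c("screening_control", "LRL")
  dm <- sum(w[cases] * geo$slice_mean[cases]) / sum(w[cases]) -
    sum(w[ctrls] * geo$slice_mean[ctrls]) / sum(w[ctrls])
  sigma <- sqrt(mom$prs_var)
  delta <- sqrt(2) * sigma * qnorm(target_auc)
  A <- mom$cov_prs_wprs_per_scale * dm
  B <- mom$wprs_var_per_scale2
  if (A^2 <= delta^2 * B)
    stopf("target AUC %.3f unattainable: max gap %.2f alleles, need %.2f",
          target_auc, A / sqrt(B), delta)
  s <- delta * config$liability_noise_sd / sqrt(A^2 - delta^2 * B)
  list(effect_scale = s, predicted_delta = delta, prs_sd = sigma)
}

#' Draw a synthetic SNP panel
#'
#' Risk-allele frequencies are i.i.d. uniform on `raf_range`; per-allele
#' log-odds weights are uniform on `weight_range` times `effect_scale`.
#' Alleles alternate over non-ambiguous pairs so no strand warning is
#' triggered. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed`).
#' @return A [snp_panel()].
#' @export
draw_panel <- function(config, seed = config$seed) {
  m <- config$m_variants
  set.seed(seed)
  raf <- runif(m, config$raf_range[1], config$raf_range[2])
  u <- runif(m, config$weight_range[1], config$weight_range[2])
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  pick <- ((seq_len(m) - 1) %% 4) + 1
  snp_panel(variant_id = sprintf("sim%04d", seq_len(m)),
            chromosome = as.character(((seq_len(m) - 1) %% 22) + 1),
            position = 1e4 + 1000 * seq_len(m),
            effect_allele = pairs[pick, 1],
            other_allele = pairs[pick, 2],
            weight = config$effect_scale * u,
            risk_allele_freq = raf,
            info_score = runif(m, 0.8, 1))
}

#' Simulate Hardy-Weinberg genotypes for a panel
#'
#' Dosages are independent `Binomial(2, p_j)` draws, so HWE holds by
#' construction.
#'
#' @param panel A [snp_panel()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(panel, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  m <- nrow(panel)
  d <- matrix(rbinom(n * m, 2, rep(panel$risk_allele_freq, each = n)), n, m,
              dimnames = list(sprintf("S%05d", seq_len(n)), panel$variant_id))
  genotype_matrix(d)
}

#' Assign ordered outcome categories from a liability
#'
#' Liability = centered weighted score + Gaussian noise; the seven ordered
#' categories are cut from the realized liability ranks so that the category
#' counts match the configured prevalences exactly. Higher categories
#' therefore carry higher expected scores whenever the effect scale is
#' positive.
#'
#' @param wprs Weighted polygenic score per sample (the genetic liability
#'   component).
#' @param config A [sim_config()].
#' @param seed Seed for the noise draw.
#' @return List with `risk_group` (ordered factor), `liability`, and the
#'   liability `thresholds` between consecutive categories.
#' @export
assign_outcomes <- function(wprs, config, seed = config$seed) {
  n <- length(wprs)
  set.seed(seed)
  liab <- (wprs - mean(wprs)) + rnorm(n, 0, config$liability_noise_sd)
  prev <- config$category_prevalences[risk_group_levels()]
  counts <- diff(c(0, round(cumsum(prev) * n)))
  grp_idx <- rep(seq_len(7), counts)
  ord <- order(liab)
  risk_group <- integer(n)
  risk_group[ord] <- grp_idx
  risk_group <- factor(risk_group_levels()[risk_group],
                       levels = risk_group_levels(), ordered = TRUE)
  bounds <- cumsum(counts)[1:6]
  thresholds <- (sort(liab)[pmax(bounds, 1)] +
                   sort(liab)[pmin(bounds + 1, n)]) / 2
  list(risk_group = risk_group, liability = liab, thresholds = thresholds)
}

#' Simulate FIT results given outcome categories
#'
#' Bernoulli positivity with each category's probability; categories with
#' `NA` probability (outside the screening programme) are `not_tested`.
#'
#' @param groups Factor of risk groups.
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return Character vector: `"positive"`, `"negative"`, `"not_tested"`.
#' @export
simulate_fit <- function(groups, config, seed = config$seed) {
  fp <- config$fit_positive_prob[as.character(groups)]
  set.seed(seed)
  u <- runif(length(groups))
  ifelse(is.na(fp), "not_tested", ifelse(u < fp, "positive", "negative"))
}

#' Simulate a full screening cohort
#'
#' Runs the whole generator under seeds derived from `config$seed`: panel,
#' HWE genotypes, liability-based outcomes, covariates (sex, age, array,
#' family history, drawn independently of genotype), FIT results, and an
#' optional array batch artifact on the dosages.
#'
#' @param config A [sim_config()].
#' @return A `simulated_cohort` list: `panel`, `geno` ([genotype_matrix()]),
#'   `cohort` ([cohort_table()]), and `truth` (liability, thresholds,
#'   weighted score, config, seed).
#' @export
simulate_cohort <- function(config = sim_config()) {
  seed <- config$seed
  panel <- draw_panel(config, seed = seed)
  geno <- simulate_genotypes(panel, config$n_population, seed = seed + 1L)
  wprs <- as.numeric(unclass(geno) %*% panel$weight)
  out <- assign_outcomes(wprs, config, seed = seed + 2L)

  n <- config$n_population
  set.seed(seed + 3L)
  sex <- ifelse(runif(n) < config$prop_female, "female", "male")
  age <- pmax(50, pmin(74, round(rnorm(n, 60, 6))))
  arr <- ifelse(runif(n) < 0.5, "array_A", "array_B")
  fh <- sample(c("yes", "no", "unknown"), n, replace = TRUE,
               prob = c(0.07, 0.91, 0.02))
  fit <- simulate_fit(out$risk_group, config, seed = seed + 4L)

  if (config$batch_effect != 0) {
    shift <- config$batch_effect / ncol(geno)
    g <- unclass(geno)
    g[arr == "array_B", ] <- pmin(2, pmax(0, g[arr == "array_B", ] + shift))
    geno <- genotype_matrix(g)
  }

  cohort <- cohort_table(sample_id = rownames(geno), sex = sex, age = age,
                         array = arr, family_history = fh,
                         fit_result = fit, risk_group = out$risk_group)
  structure(list(panel = panel, geno = geno, cohort = cohort,
                 truth = list(liability = out$liability,
                              thresholds = out$thresholds,
                              wprs = wprs, config = config, seed = seed)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d samples x %d variants (seed %d)\n",
              nrow(x$geno), ncol(x$geno), x$truth$seed))
  print(table(x$cohort$risk_group))
  invisible(x)
}

#' FIT-stratified sampling of the screening study
#'
#' Restricts to the screening-programme groups (screening controls through
#' screen-detected CRC), keeps every FIT-positive participant and each
#' FIT-negative with probability `fitneg_retention`, and attaches the
#' population FIT-stratum weights (the FIT-positive and FIT-negative
#' fractions among all tested participants of the source cohort), which by
#' construction sum to 1 and play the role of the 0.06 / 0.94 sampling
#' weights of a real programme.
#'
#' @param sim A [simulate_cohort()] result.
#' @param config A [sim_config()] (defaults to the one used to simulate).
#' @param seed Seed for the retention draws.
#' @return List with `geno`, `cohort` (the sampled subset), `weights`
#'   (`c(w_pos, w_neg)`), and `index` into the source cohort.
#' @export
sample_screening <- function(sim, config = sim$truth$config,
                             seed = config$seed + 5L) {
  ch <- sim$cohort
  eligible <- as.character(ch$risk_group) %in% screening_levels()
  tested <- eligible & ch$fit_result != "not_tested"
  pos <- tested & ch$fit_result == "positive"
  neg <- tested & ch$fit_result == "negative"
  if (!any(tested)) stopf("no tested participants to sample")
  set.seed(seed)
  keep_neg <- neg & (runif(nrow(ch)) < config$fitneg_retention)
  if (any(neg) && !any(keep_neg))
    stopf("no FIT-negative participant retained; increase fitneg_retention")
  idx <- which(pos | keep_neg)
  w_pos <- sum(pos) / sum(tested)
  sub_cohort <- ch[idx, , drop = FALSE]
  class(sub_cohort) <- class(ch)
  list(geno = genotype_matrix(unclass(sim$geno)[idx, , drop = FALSE]),
       cohort = sub_cohort,
       weights = c(w_pos = w_pos, w_neg = 1 - w_pos),
       index = idx)
}
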