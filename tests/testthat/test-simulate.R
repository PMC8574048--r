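test_that("the generator is bit-for-bit reproducible under a fixed config", {
  cfg <- sim_config(n_population = 2000, seed = 91)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$geno), unclass(b$geno))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$liability, b$truth$liability)
  expect_identical(draw_panel(cfg), draw_panel(cfg))
  # a different seed changes the draws
  c_ <- simulate_cohort(sim_config(n_population = 2000, seed = 92))
  expect_false(identical(unclass(a$geno), unclass(c_$geno)))
})

test_that("simulated genotypes sit in Hardy-Weinberg proportions", {
  p <- 0.5
  panel <- toy_panel(1, raf = p)
  g <- simulate_genotypes(panel, 20000, seed = 93)
  tab <- table(factor(unclass(g)[, 1], levels = 0:2)) / 20000
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.03)
  expect_gt(hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))$p, 1e-4)
  # near-zero frequency gives (almost) all zero dosages
  rare <- toy_panel(1, raf = 0.001)
  g0 <- simulate_genotypes(rare, 500, seed = 94)
  expect_lte(sum(unclass(g0)), 3)
})

test_that("effect_scale 0 produces a null panel and null discrimination", {
  cfg <- sim_config(effect_scale = 0, n_population = 12000, seed = 95)
  expect_true(all(draw_panel(cfg)$weight == 0))
  sim <- simulate_cohort(cfg)
  scr <- sample_screening(sim)
  g <- group_outcomes(scr$cohort, "primary_screening")
  sc <- compute_scores(scr$geno, sim$panel)
  x <- sc$prs[match(g$sample_id, sc$sample_id)]
  cv <- cv_auc(x, g$label, seed = 95)
  expect_lt(abs(cv$auc - 0.5), 0.07)
})

test_that("outcome categories match the configured prevalences exactly", {
  cfg <- sim_config(n_population = 10000, seed = 96)
  sim <- simulate_cohort(cfg)
  counts <- as.integer(table(sim$cohort$risk_group))
  expect_equal(counts,
               unname(diff(c(0, round(cumsum(cfg$category_prevalences) *
                                        10000)))))
  # higher categories carry higher mean liability and mean PRS trend
  sc <- compute_scores(sim$geno, sim$panel)
  means <- tapply(sc$prs, sim$cohort$risk_group, mean)
  expect_lt(mann_kendall_test(as.numeric(means))$p, 0.05)
  expect_gt(cor(as.integer(sim$cohort$risk_group), sim$truth$liability,
                method = "spearman"), 0.5)
})

test_that("FIT positivity follows the category-conditional probabilities", {
  cfg <- sim_config(seed = 97)
  sim <- simulate_cohort(cfg)
  ch <- sim$cohort
  expect_true(all(ch$fit_result[ch$risk_group == "population_control"] ==
                    "not_tested"))
  expect_true(all(ch$fit_result[ch$risk_group == "clinical_CRC"] ==
                    "not_tested"))
  crc <- ch$fit_result[ch$risk_group == "screening_CRC"]
  expect_gt(mean(crc == "positive"), 0.9)  # nominal 0.985
  tested <- ch$fit_result != "not_tested"
  fit_pos_rate <- mean(ch$fit_result[tested] == "positive")
  expect_gt(fit_pos_rate, 0.05)            # ~6% positives in the population
  expect_lt(fit_pos_rate, 0.08)
  # probability 0 for a category makes everyone negative
  cfg0 <- sim_config(fit_positive_prob = c(
    population_control = NA, screening_control = 0, LRL = 0, IRL = 0,
    HRL = 0, screening_CRC = 0, clinical_CRC = NA), seed = 97)
  fr <- simulate_fit(ch$risk_group, cfg0, seed = 98)
  expect_false(any(fr == "positive"))
})

test_that("FIT-stratified sampling reproduces the design margins", {
  cfg <- sim_config(seed = 99)
  sim <- simulate_cohort(cfg)
  scr <- sample_screening(sim)
  frac_pos <- mean(scr$cohort$fit_result == "positive")
  expect_gt(frac_pos, 0.72)  # design target ~0.77
  expect_lt(frac_pos, 0.82)
  expect_equal(sum(scr$weights), 1)
  expect_lt(abs(scr$weights[["w_pos"]] - 0.065), 0.02)
  expect_true(all(scr$cohort$risk_group %in%
                    c("screening_control", "LRL", "IRL", "HRL",
                      "screening_CRC")))
  # retention 1 keeps every tested participant
  cfg1 <- sim_config(fitneg_retention = 1, n_population = 3000, seed = 100)
  sim1 <- simulate_cohort(cfg1)
  scr1 <- sample_screening(sim1)
  tested <- sim1$cohort$fit_result != "not_tested"
  expect_equal(nrow(scr1$cohort), sum(tested))
})

test_that("effect calibration inverts the binormal identity and round-trips", {
  cfg <- sim_config(seed = 101)
  expect_equal(calibrate_effects(0.5, cfg)$effect_scale, 0)
  cal <- calibrate_effects(0.56, cfg)
  expect_equal(cal$predicted_delta, sqrt(2) * cal$prs_sd * qnorm(0.56),
               tolerance = 1e-10)
  expect_equal(cal$prs_sd, 7.23, tolerance = 0.01)
  expect_error(calibrate_effects(0.99, cfg), "unattainable")
  # round trip: the raw-PRS AUC on screening case/control matches the target
  aucs <- vapply(1:5, function(s) {
    sim <- simulate_cohort(sim_config(seed = 200 + s))
    scr <- sample_screening(sim)
    g <- group_outcomes(scr$cohort, "primary_screening")
    sc <- compute_scores(scr$geno, sim$panel)
    roc_auc(sc$prs[match(g$sample_id, sc$sample_id)], g$label,
            ci = FALSE)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.56), 0.015)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(category_prevalences = c(
    population_control = 0.5, screening_control = 0.5, LRL = 0.2, IRL = 0,
    HRL = 0, screening_CRC = 0, clinical_CRC = 0)), "sum to 1")
  expect_error(sim_config(raf_range = c(0, 0.9)), "inside")
  expect_error(sim_config(fitneg_retention = 0), "fitneg_retention")
  expect_error(sim_config(fit_positive_prob = c(
    population_control = NA, screening_control = 0.5, LRL = 0.06, IRL = 0.15,
    HRL = 0.30, screening_CRC = 0.985, clinical_CRC = NA)), "non-decreasing")
})
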