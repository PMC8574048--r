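test_that("HWE chi-square test matches hand-computed values", {
  # exact HWE proportions: chi-square 0, p 1
  r <- hwe_test(25, 50, 25)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # no heterozygotes at p = 0.5: expected (25, 50, 25) -> chi-square 100
  r <- hwe_test(50, 0, 50)
  expect_equal(r$chisq, 100)
  expect_equal(r$p, pchisq(100, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_lt(r$p, 1e-22)
  # (30, 40, 30): expected (25, 50, 25) -> 25/25 + 100/50 + 25/25 = 4
  r <- hwe_test(30, 40, 30)
  expect_equal(r$chisq, 4)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(r$p, 4), 0.0455)
})

test_that("monomorphic sites fit HWE trivially", {
  expect_equal(hwe_test(100, 0, 0)$p, 1)
  expect_equal(hwe_test(0, 0, 100)$p, 1)
  expect_error(hwe_test(0, 0, 0), "no genotypes")
  expect_error(hwe_test(-1, 5, 5), "non-negative")
})

make_qc_fixture <- function() {
  # 100 samples x 5 variants, all in good shape by construction
  set.seed(11)
  panel <- toy_panel(5, raf = c(0.3, 0.4, 0.5, 0.2, 0.5))
  d <- sapply(panel$risk_allele_freq, function(p) rbinom(100, 2, p))
  list(panel = panel, geno = toy_geno(d, panel))
}

test_that("variant QC excludes on missingness, info, MAF and HWE with reasons", {
  fx <- make_qc_fixture()
  d <- unclass(fx$geno)
  d[1:6, 1] <- NA                      # 6% missing -> fails the 5% rule
  d[, 2] <- rep(c(0, 2), 50)           # no heterozygotes -> HWE failure
  d[, 3] <- c(2, rep(0, 99))           # MAF 0.01 still passes; then rarer:
  d[, 3] <- c(rep(0, 100))             # monomorphic: MAF 0 -> fails MAF
  panel <- fx$panel
  panel$info_score <- c(NA, NA, NA, 0.29, NA)  # v4 fails the info filter
  g <- genotype_matrix(d)
  res <- qc_variants(g, panel)
  rep_ <- res$report
  expect_equal(rep_$reason[rep_$variant_id == "v1"], "missingness")
  expect_match(rep_$reason[rep_$variant_id == "v2"], "hwe")
  expect_match(rep_$reason[rep_$variant_id == "v3"], "maf")
  expect_equal(rep_$reason[rep_$variant_id == "v4"], "info")
  expect_equal(sum(rep_$pass) + sum(!rep_$pass), nrow(panel))
  expect_error(qc_variants(g, panel, qc_thresholds(missing = 0, maf = 0.5,
                                                   hwe_p = 0.5, info = 1)),
               "no variant survives")
})

test_that("QC passes everything through untouched when all rules hold", {
  fx <- make_qc_fixture()
  res <- qc_variants(fx$geno, fx$panel)
  expect_equal(unclass(res$geno), unclass(fx$geno))
  expect_true(all(res$report$pass))
  # idempotence: a second pass changes nothing
  res2 <- qc_variants(res$geno, res$panel)
  expect_equal(unclass(res2$geno), unclass(res$geno))
  expect_equal(res2$panel$variant_id, res$panel$variant_id)
})

test_that("HWE can be restricted to a sample subset", {
  fx <- make_qc_fixture()
  d <- unclass(fx$geno)
  # make HWE fail only within the first 50 samples
  d[1:50, 2] <- rep(c(0, 2), 25)
  d[51:100, 2] <- rbinom(50, 2, 0.5)
  g <- genotype_matrix(d)
  res_all <- qc_variants(g, fx$panel)
  res_ctrl <- qc_variants(g, fx$panel,
                          hwe_samples = rownames(g)[51:100])
  expect_lt(res_all$report$hwe_p[2], res_ctrl$report$hwe_p[2])
  expect_error(qc_variants(g, fx$panel, hwe_samples = "nobody"),
               "matches no")
})

test_that("sample QC removes samples above the missingness threshold", {
  cfg <- sim_config(seed = 3)
  panel <- draw_panel(cfg)
  g <- simulate_genotypes(panel, 5, seed = 4)
  d <- unclass(g)
  d[1, 1:2] <- NA    # 2 of 133 = 1.5% missing -> removed at the 1% default
  d[2, 1] <- NA      # 0.75% -> retained
  g <- genotype_matrix(d)
  res <- qc_samples(g)
  expect_false("S00001" %in% rownames(res$geno))
  expect_true("S00002" %in% rownames(res$geno))
  expect_equal(res$report$reason[1], "missingness")
  # vacuous threshold keeps everyone
  expect_equal(nrow(qc_samples(g, threshold = 1)$geno), 5)
})
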