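two_pop_geno <- function(n_per = 200, m = 200, div = 0.2, seed = 31) {
  set.seed(seed)
  p1 <- runif(m, 0.2, 0.8)
  p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-div, div), m, TRUE)))
  d <- rbind(sapply(p1, function(p) rbinom(n_per, 2, p)),
             sapply(p2, function(p) rbinom(n_per, 2, p)))
  dimnames(d) <- list(sprintf("s%03d", seq_len(2 * n_per)),
                      sprintf("v%03d", seq_len(m)))
  list(geno = genotype_matrix(d),
       pop = rep(c("A", "B"), each = n_per))
}

test_that("PC1 separates two diverged populations without overlap", {
  fx <- two_pop_geno()
  pcs <- genotype_pca(fx$geno, K = 2)
  a <- pcs$scores[fx$pop == "A", 1]
  b <- pcs$scores[fx$pop == "B", 1]
  expect_true(max(a) < min(b) || max(b) < min(a))
  expect_gt(pcs$var_explained[1], pcs$var_explained[2])
})

test_that("a homogeneous population has no dominant component", {
  set.seed(32)
  p <- runif(200, 0.2, 0.8)
  d <- sapply(p, function(pp) rbinom(300, 2, pp))
  dimnames(d) <- list(sprintf("s%03d", 1:300), sprintf("v%03d", 1:200))
  pcs <- genotype_pca(genotype_matrix(d), K = 3)
  # leading share of variance stays near 1/rank, far from structure-like
  expect_lt(pcs$var_explained[1], 0.03)
  expect_gt(pcs$var_explained[1], 1 / 200)
})

test_that("duplicating every sample leaves component directions unchanged", {
  fx <- two_pop_geno(n_per = 60, m = 80, seed = 33)
  d <- unclass(fx$geno)
  dup <- rbind(d, d)
  rownames(dup) <- sprintf("s%03d", seq_len(nrow(dup)))
  p1 <- genotype_pca(fx$geno, K = 2)
  p2 <- genotype_pca(genotype_matrix(dup), K = 2)
  for (k in 1:2)
    expect_gt(abs(cor(p1$loadings[, k], p2$loadings[, k])), 0.999)
})

test_that("full-rank PCA reconstructs the standardized matrix", {
  set.seed(34)
  p <- runif(12, 0.2, 0.8)
  d <- sapply(p, function(pp) rbinom(30, 2, pp))
  dimnames(d) <- list(sprintf("s%02d", 1:30), sprintf("v%02d", 1:12))
  keep <- apply(d, 2, function(x) length(unique(x)) > 1)
  d <- d[, keep]
  pcs <- genotype_pca(genotype_matrix(d), K = min(dim(d)) - 0)
  p_hat <- colMeans(d) / 2
  X <- sweep(sweep(d, 2, 2 * p_hat, "-"), 2,
             sqrt(2 * p_hat * (1 - p_hat)), "/")
  expect_equal(pcs$scores %*% t(pcs$loadings), X, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("nearest-centroid ancestry assignment is deterministic and accurate", {
  ref <- ancestry_reference()
  # a sample at a centroid gets that label
  cent <- colMeans(ref[ref$label == "AFR", -1])
  got <- assign_ancestry(matrix(cent, 1, dimnames = list("s1", names(cent))),
                         ref)
  expect_equal(got$ancestry, "AFR")
  expect_false(got$tie)
  # equidistant point: deterministic tie-break by label order, flagged
  ref2 <- data.frame(label = c("P1", "P2"), PC1 = c(-1, 1), PC2 = 0)
  got <- assign_ancestry(matrix(c(0, 0), 1,
                                dimnames = list("s1", c("PC1", "PC2"))), ref2)
  expect_equal(got$ancestry, "P1")
  expect_true(got$tie)
  expect_error(assign_ancestry(matrix(0, 1, 1), ref2[0, ]), "empty")
})

test_that("held-out points from three synthetic populations assign correctly", {
  set.seed(35)
  centers <- ancestry_reference()
  labs <- unique(centers$label)
  pts <- do.call(rbind, lapply(labs, function(l) {
    mu <- colMeans(centers[centers$label == l, c("PC1", "PC2")])
    cbind(PC1 = rnorm(100, mu[1], 0.8), PC2 = rnorm(100, mu[2], 0.8))
  }))
  rownames(pts) <- sprintf("s%03d", seq_len(nrow(pts)))
  got <- assign_ancestry(pts, centers)
  expect_gte(mean(got$ancestry == rep(labs, each = 100)), 0.99)
})

adjust_fixture <- function(n = 400, seed = 41) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             sex = sample(c("female", "male"), n, TRUE),
             age = round(runif(n, 50, 74)),
             array = sample(c("array_A", "array_B"), n, TRUE),
             family_history = sample(c("yes", "no", "unknown"), n, TRUE,
                                     prob = c(0.1, 0.85, 0.05)),
             stringsAsFactors = FALSE)
}

test_that("constant covariates leave the PRS unchanged", {
  ch <- adjust_fixture(50)
  ch$sex <- "female"; ch$age <- 60; ch$array <- "array_A"
  ch$family_history <- "no"
  sc <- data.frame(sample_id = ch$sample_id, prs = rnorm(50, 133, 7))
  expect_warning(adj <- adjust_prs(sc, ch), "constant covariate")
  expect_equal(adj$adjusted_prs, sc$prs)
})

test_that("a PRS exactly linear in age adjusts to a constant", {
  ch <- adjust_fixture(100)
  sc <- data.frame(sample_id = ch$sample_id, prs = 100 + 0.5 * ch$age)
  adj <- adjust_prs(sc, ch)
  expect_equal(adj$adjusted_prs, rep(mean(sc$prs), 100), tolerance = 1e-8)
})

test_that("an injected array batch offset is removed by adjustment", {
  ch <- adjust_fixture(2000, seed = 42)
  set.seed(43)
  prs <- rnorm(2000, 133, 7.2) + ifelse(ch$array == "array_B", 1.0, 0)
  sc <- data.frame(sample_id = ch$sample_id, prs = prs)
  raw_gap <- mean(prs[ch$array == "array_B"]) - mean(prs[ch$array == "array_A"])
  expect_gt(raw_gap, 0.5)
  adj <- adjust_prs(sc, ch)
  gap <- mean(adj$adjusted_prs[ch$array == "array_B"]) -
    mean(adj$adjusted_prs[ch$array == "array_A"])
  expect_lt(abs(gap), 1e-8)
  expect_equal(mean(adj$adjusted_prs), mean(prs))
})

test_that("adjusted scores are orthogonal to covariates and location-equivariant", {
  ch <- adjust_fixture(500, seed = 44)
  set.seed(45)
  sc <- data.frame(sample_id = ch$sample_id,
                   prs = rnorm(500, 133, 7) + 0.2 * ch$age)
  pcs <- matrix(rnorm(500 * 5), 500, 5,
                dimnames = list(ch$sample_id, paste0("PC", 1:5)))
  adj <- adjust_prs(sc, ch, pcs)
  expect_lt(abs(cov(adj$adjusted_prs, ch$age)), 1e-8)
  for (k in 1:5)
    expect_lt(abs(cov(adj$adjusted_prs, pcs[, k])), 1e-8)
  expect_lt(abs(cov(adj$adjusted_prs, as.numeric(ch$sex == "male"))), 1e-8)
  # adding a constant shifts the adjusted score by the same constant
  sc2 <- transform(sc, prs = prs + 5)
  adj2 <- adjust_prs(sc2, ch, pcs)
  expect_equal(adj2$adjusted_prs, adj$adjusted_prs + 5, tolerance = 1e-10)
})
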