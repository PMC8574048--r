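#' Principal component analysis of a genotype matrix
#'
#' Each variant column is mean-centered and scaled by `sqrt(2 p (1 - p))`
#' with `p` the observed effect-allele frequency (the usual binomial
#' standardization for ancestry PCA), missing dosages are set to the column
#' mean (zero after centering), zero-variance variants are dropped, and the
#' components come from a singular value decomposition. Signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param geno A [genotype_matrix()].
#' @param K Number of components to return (default 5).
#' @return A `pc_result` list with `scores` (samples x K), `loadings`
#'   (variants x K), `var_explained` (length K fractions of total variance)
#'   and `kept_variants`.
#' @export
genotype_pca <- function(geno, K = 5) {
  stopifnot(inherits(geno, "genotype_matrix"), K >= 1)
  X <- unclass(geno)
  if (nrow(X) < K + 1) stopf("need at least K + 1 samples for K components")
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  X <- X[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  X <- sweep(X, 2, 2 * p_hat, "-")
  X <- sweep(X, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  X[is.na(X)] <- 0
  r <- min(dim(X))
  if (K > r) stopf("K = %d exceeds available rank %d", K, r)
  sv <- svd(X, nu = K, nv = K)
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_len(K)) {
    s <- sign(sv$v[which.max(abs(sv$v[, k])), k])
    if (s < 0) { sv$v[, k] <- -sv$v[, k]; sv$u[, k] <- -sv$u[, k] }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
  dimnames(scores) <- list(rownames(geno), paste0("PC", seq_len(K)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(K)))
  total_var <- sum(X^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d[seq_len(K)]^2 / total_var,
                 kept_variants = colnames(X)),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$var_explained)))
  invisible(x)
}

#' Assign ancestry labels by nearest reference centroid
#'
#' Each sample is labeled with the ancestry of the nearest centroid in
#' principal-component space (Euclidean distance over the shared
#' components). Exact ties are broken deterministically by the order of the
#' labels in the reference and flagged.
#'
#' @param pcs A [genotype_pca()] result, or a numeric matrix of coordinates.
#' @param reference Data frame with a `label` column and PC coordinate
#'   columns matching the names in `pcs` (e.g. `PC1`, `PC2`, ...). Rows with
#'   the same label are averaged into one centroid.
#' @return Data frame with `sample_id`, `ancestry`, `distance`, `tie`.
#' @export
assign_ancestry <- function(pcs, reference) {
  coords <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
  if (!nrow(reference)) stopf("empty ancestry reference")
  if (!"label" %in% names(reference)) stopf("reference needs a 'label' column")
  pc_cols <- intersect(colnames(coords), names(reference))
  if (!length(pc_cols)) stopf("reference shares no PC columns with the scores")
  labs <- unique(reference$label)
  centroids <- t(vapply(labs, function(l)
    colMeans(reference[reference$label == l, pc_cols, drop = FALSE]),
    numeric(length(pc_cols))))
  X <- coords[, pc_cols, drop = FALSE]
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") - 2 * X %*% t(centroids)
  d2[d2 < 0] <- 0
  best <- apply(d2, 1, which.min)  # which.min breaks ties by first (label order)
  mind <- d2[cbind(seq_len(nrow(d2)), best)]
  tie <- vapply(seq_len(nrow(d2)), function(i)
    sum(abs(d2[i, ] - mind[i]) < 1e-12) > 1, logical(1))
  data.frame(sample_id = rownames(coords) %||% seq_len(nrow(X)),
             ancestry = labs[best],
             distance = sqrt(mind),
             tie = tie,
             stringsAsFactors = FALSE)
}

#' Load the bundled synthetic ancestry reference centroids
#'
#' A small synthetic stand-in for a labeled external reference panel:
#' centroid coordinates for three ancestry clusters on the first five
#' principal components, constructed for testing and examples (it is not
#' derived from any real reference data set).
#'
#' @return Data frame with columns `label`, `PC1`..`PC5`.
#' @export
ancestry_reference <- function() {
  read.delim(system.file("extdata", "ancestry_reference_synthetic.tsv",
                         package = "prscreen"),
             stringsAsFactors = FALSE)
}
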