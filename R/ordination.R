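# Condition-signature views: expression filtering, exact PCA of samples on
# log2(FPKM + 1), and Ward hierarchical clustering on Spearman-correlation
# distance.

#' Filter to expressed genes
#'
#' Retains genes whose maximum FPKM across samples is strictly greater than
#' `min_fpkm` (the "FPKM > 5" inclusion rule at the default).
#'
#' @param expr an `ExpressionMatrix`.
#' @param min_fpkm strict lower bound (default 5).
#' @param aggregate `"max"` (default) or `"mean"` across samples.
#' @return filtered `ExpressionMatrix`.
#' @export
filter_expressed <- function(expr, min_fpkm = 5, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stat <- if (aggregate == "max") apply(expr$values, 1, max)
  else rowMeans(expr$values)
  keep <- stat > min_fpkm
  if (!any(keep)) {
    stop_bn("no gene exceeds FPKM %s; lower the threshold", format(min_fpkm))
  }
  expression_matrix(expr$values[keep, , drop = FALSE], expr$meta)
}

#' Principal components analysis of samples
#'
#' Samples are points in gene space after `log2(FPKM + 1)` transform and
#' per-gene centering; components come from the exact singular value
#' decomposition. Per-component variance-explained fractions are
#' eigenvalues over their sum. Component signs follow a deterministic
#' convention: the gene with the largest absolute loading gets a positive
#' loading.
#'
#' @param expr an `ExpressionMatrix` (pre-filtered as appropriate).
#' @param log_transform apply log2(FPKM + 1) first? (default TRUE)
#' @return list of class `OrdinationResult`: `scores` (samples x components),
#'   `loadings`, `var_explained`, `center`.
#' @export
pca_samples <- function(expr, log_transform = TRUE) {
  X <- t(expr$values) # samples x genes
  assert_that(nrow(X) >= 2, "need at least 2 samples")
  if (log_transform) X <- log2(X + 1)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  ncomp <- sum(sv$d > sv$d[1] * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d, ncomp)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncomp)))
  dimnames(V) <- list(colnames(X), colnames(scores))
  structure(list(scores = scores, loadings = V,
                 var_explained = d^2 / sum(sv$d^2), center = ctr),
            class = "OrdinationResult")
}

#' Ward hierarchical clustering of samples on Spearman distance
#'
#' Pairwise distance `d(i, j) = 1 - spearman_rho(i, j)` over genes, followed
#' by Ward agglomeration in its squared-distance (Lance-Williams) form —
#' the `ward.D2` variant. A constant sample profile makes rho undefined and
#' is an error naming the sample.
#'
#' @param expr an `ExpressionMatrix`.
#' @return an object of class `hclust`.
#' @export
hcluster_samples <- function(expr) {
  X <- expr$values
  assert_that(ncol(X) >= 2, "need at least 2 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_bn("constant expression profile, Spearman correlation undefined for sample '%s'",
            colnames(X)[which(sds == 0)[1]])
  }
  rho <- stats::cor(X, method = "spearman")
  d <- stats::as.dist(1 - rho)
  stats::hclust(d, method = "ward.D2")
}
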