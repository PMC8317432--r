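#' Method-of-moments pairwise relatedness from dosages
#'
#' Uses complete-case SNPs only. Each individual's dosage is centred by
#' 4 qhat per site (qhat the overall sample allele frequency); relatedness
#' is the correlation-form moment estimator
#' r_ij = sum_l c_il c_jl / sqrt(sum_l c_il^2 * sum_l c_jl^2),
#' bounded in [-1, 1] with unit self-relatedness.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @return symmetric individuals x individuals matrix, unit diagonal.
#' @export
relatedness_matrix <- function(dosage) {
  if (inherits(dosage, "tetra_genotypes")) dosage <- dosage$dosage
  complete <- colSums(is.na(dosage)) == 0
  if (!any(complete)) stop("no complete-case SNPs")
  g <- dosage[, complete, drop = FALSE]
  qhat <- colMeans(g) / 4
  C <- sweep(g, 2, 4 * qhat)
  norms <- sqrt(rowSums(C^2))
  zero <- norms == 0
  if (any(zero))
    stop("individual(s) with zero dosage variance across loci: ",
         paste(rownames(g)[zero], collapse = ", "))
  R <- tcrossprod(C / norms)
  diag(R) <- 1
  R
}

#' PCA of individuals on the covariance of allele frequencies
#'
#' Column-centres the dosage matrix (optionally mean-imputing missing
#' cells, else restricting to complete-case sites) and eigendecomposes the
#' individual x individual covariance. The sign of each component is fixed
#' so that its largest-magnitude loading is positive, making scores
#' reproducible bit-identically under fixed input ordering.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @param n_components number of components to return.
#' @param impute_missing mean-impute missing cells instead of dropping
#'   incomplete sites.
#' @param scale_sites scale sites to unit variance before decomposition
#'   (default FALSE: pure covariance).
#' @return An object of class `"dosage_pca"`: list with `scores`
#'   (individuals x components), `explained_pct` (all components, summing
#'   to 100), `n_components`. Supports `print()` and `plot()`.
#' @export
pca_dosage <- function(dosage, n_components = 3, impute_missing = TRUE,
                       scale_sites = FALSE) {
  if (inherits(dosage, "tetra_genotypes")) dosage <- dosage$dosage
  if (nrow(dosage) < 2 || ncol(dosage) < 2)
    stop("need at least 2 individuals and 2 sites")
  X <- dosage
  if (impute_missing) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  } else {
    X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
    if (ncol(X) < 2) stop("fewer than 2 complete-case sites")
  }
  Xc <- sweep(X, 2, colMeans(X))
  if (scale_sites) {
    s <- apply(X, 2, stats::sd)
    keep <- s > 0
    Xc <- sweep(Xc[, keep, drop = FALSE], 2, s[keep], "/")
  }
  cov_ind <- tcrossprod(Xc) / (ncol(Xc) - 1)
  e <- eigen(cov_ind, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components truncated to rank %d", rank))
    n_components <- rank
  }
  scores <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_components)]), n_components)
  # sign convention: largest-magnitude element of each axis positive
  for (k in seq_len(n_components)) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(rownames(dosage),
                           paste0("PC", seq_len(n_components)))
  structure(list(scores = scores,
                 explained_pct = 100 * ev / sum(ev),
                 n_components = n_components),
            class = "dosage_pca")
}

#' @export
print.dosage_pca <- function(x, ...) {
  cat(sprintf("PCA on dosage covariance: %d individuals, %d components kept\n",
              nrow(x$scores), x$n_components))
  cat(sprintf("explained by PC1..PC%d: %s%%\n", x$n_components,
              paste(sprintf("%.1f", x$explained_pct[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.dosage_pca <- function(x, components = c(1, 2), col = 1, ...) {
  graphics::plot(x$scores[, components[1]], x$scores[, components[2]],
                 col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                x$explained_pct[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                x$explained_pct[components[2]]),
                 ...)
  invisible(x)
}
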