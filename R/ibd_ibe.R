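#' Pairwise geographic distances between localities
#'
#' Haversine great-circle distances (Earth radius 6371.0088 km), optionally
#' natural-log transformed for distance-matrix regression.
#'
#' @param pops locality table with `lat`/`lon` in decimal degrees.
#' @param log_transform return log(km) instead of km.
#' @return symmetric localities x localities matrix (km or log km).
#' @export
geographic_distance <- function(pops, log_transform = FALSE) {
  xy <- as.matrix(pops[, c("lon", "lat")])
  J <- nrow(xy)
  d <- matrix(0, J, J, dimnames = list(pops$locality, pops$locality))
  for (i in seq_len(J - 1)) {
    km <- geosphere::distHaversine(xy[i, ], xy[(i + 1):J, , drop = FALSE],
                                   r = 6371.0088)
    d[i, (i + 1):J] <- d[(i + 1):J, i] <- km
  }
  if (log_transform) {
    off <- d[upper.tri(d)]
    if (any(off <= 0))
      stop("zero off-diagonal distance; log transform undefined")
    d[upper.tri(d) | lower.tri(d)] <- log(d[upper.tri(d) | lower.tri(d)])
  }
  d
}

#' Linearize an F_ST matrix for distance-matrix regression
#'
#' @param fst symmetric F_ST matrix with entries in [0, 1).
#' @return fst / (1 - fst), elementwise, zero diagonal preserved.
#' @export
linearize_fst <- function(fst) {
  if (any(fst[upper.tri(fst)] >= 1)) stop("F_ST of 1 cannot be linearized")
  fst / (1 - fst)
}

#' Greedy collinearity pruning of covariates
#'
#' While any covariate pair exceeds `cutoff` in absolute Pearson
#' correlation, removes from the worst offending pair the variable with the
#' larger mean absolute correlation against all remaining variables (ties
#' broken by name). Constant covariates are removed first with a warning.
#'
#' @param covariates data.frame/matrix, localities x covariates.
#' @param cutoff absolute-correlation threshold.
#' @return character vector of retained covariate names.
#' @export
prune_collinear <- function(covariates, cutoff = 0.9) {
  X <- as.data.frame(covariates)
  if (ncol(X) < 2) return(names(X))
  const <- vapply(X, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning("constant covariate(s) removed: ",
            paste(names(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  keep <- sort(names(X))
  repeat {
    if (length(keep) < 2) break
    r <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= cutoff) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- rowMeans(r[pair, , drop = FALSE])
    drop_var <- pair[order(-mean_abs, pair)][1]
    keep <- setdiff(keep, drop_var)
  }
  keep
}

#' Environmental distances between localities
#'
#' Z-scores each selected covariate across localities (making the result
#' scale invariant) and takes Euclidean distances.
#'
#' @param covariates localities x covariates table (rownames = localities).
#' @param selected covariate names to use.
#' @return symmetric distance matrix.
#' @export
environmental_distance <- function(covariates, selected = colnames(covariates)) {
  if (length(selected) < 1) stop("no covariates selected")
  X <- as.matrix(covariates[, selected, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 localities")
  Z <- scale(X)
  Z[, apply(X, 2, stats::sd) == 0] <- 0  # constant covariates add no distance
  d <- as.matrix(stats::dist(Z))
  dimnames(d) <- list(rownames(covariates), rownames(covariates))
  d
}

lower_vec <- function(m) m[lower.tri(m)]

# permute rows and columns of a square matrix jointly
permute_matrix <- function(m, idx) m[idx, idx]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle vectors, with significance by
#' simultaneous random row/column permutation of the second matrix;
#' one-sided (greater) p = (1 + #{r_perm >= r_obs}) / (n_perm + 1).
#'
#' @param A,B conformable symmetric distance matrices.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = NULL) {
  stopifnot(all(dim(A) == dim(B)))
  a <- lower_vec(A)
  if (stats::sd(a) == 0 || stats::sd(lower_vec(B)) == 0)
    stop("constant off-diagonal entries; Mantel r undefined")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(a, lower_vec(B))
  J <- nrow(B)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    stats::cor(a, lower_vec(permute_matrix(B, sample.int(J))))
  }, numeric(1))
  structure(list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
                 n_perm = n_perm, partial = FALSE),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("%s: r = %.3f, p = %.3f (%d permutations)\n",
              if (isTRUE(x$partial)) "Partial Mantel test" else "Mantel test",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Partial Mantel test controlling for a third matrix
#'
#' Residualizes the lower triangles of A and B on C by simple OLS,
#' correlates the residuals, and permutes B (rows/columns jointly) for the
#' null distribution.
#'
#' @param A,B,C conformable symmetric distance matrices; C is controlled.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 999, seed = NULL) {
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(C)))
  cv <- lower_vec(C)
  res_on <- function(y) stats::lm.fit(cbind(1, cv), y)$residuals
  ra <- res_on(lower_vec(A))
  rb <- res_on(lower_vec(B))
  if (stats::sd(rb) < 1e-12)
    stop("B is (near-)constant after controlling for C; partial r undefined")
  if (stats::sd(ra) < 1e-12) {
    # A fully explained by C: nothing left to correlate
    return(structure(list(r = 0, p = 1, n_perm = n_perm, partial = TRUE),
                     class = "mantel_test"))
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(ra, rb)
  J <- nrow(B)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    stats::cor(ra, res_on(lower_vec(permute_matrix(B, sample.int(J)))))
  }, numeric(1))
  structure(list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
                 n_perm = n_perm, partial = TRUE),
            class = "mantel_test")
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' OLS of the response distance matrix's lower triangle on the predictors'
#' lower triangles. Significance of each coefficient and of the model is
#' obtained by jointly permuting rows and columns of the response matrix
#' and recomputing t- and F-statistics;
#' p = (1 + #{|t_perm| >= |t_obs|}) / (n_perm + 1).
#'
#' @param Y response distance matrix.
#' @param X named list of predictor distance matrices.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return An object of class `"mmrr"`: list with `r_squared`, `betas`
#'   (raw scale, including intercept), `betas_std` (standardized, no
#'   intercept), `beta_pvalues`, `model_pvalue`, `n_perm`. Supports
#'   `print()`.
#' @export
mmrr <- function(Y, X, n_perm = 1000, seed = NULL) {
  if (!is.list(X)) X <- list(X1 = X)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("X", seq_along(X))
  y <- lower_vec(Y)
  Xm <- cbind(`(Intercept)` = 1,
              vapply(X, lower_vec, numeric(length(y))))
  if (kappa(crossprod(Xm)) > 1e8)
    stop("predictor distance vectors are collinear; prune predictors first")
  n <- length(y); p <- ncol(Xm)
  XtXi <- solve(crossprod(Xm))
  H <- XtXi %*% t(Xm)

  fit_stats <- function(yv) {
    beta <- drop(H %*% yv)
    res <- yv - drop(Xm %*% beta)
    rss <- sum(res^2)
    tss <- sum((yv - mean(yv))^2)
    sigma2 <- rss / (n - p)
    tval <- beta / sqrt(diag(XtXi) * sigma2)
    fval <- ((tss - rss) / (p - 1)) / sigma2
    list(beta = beta, t = tval, f = fval, r2 = 1 - rss / tss)
  }
  obs <- fit_stats(y)
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(Y)
  exceed_t <- numeric(p); exceed_f <- 0
  for (k in seq_len(n_perm)) {
    st <- fit_stats(lower_vec(permute_matrix(Y, sample.int(J))))
    exceed_t <- exceed_t + (abs(st$t) >= abs(obs$t))
    exceed_f <- exceed_f + (st$f >= obs$f)
  }
  sds <- apply(Xm[, -1, drop = FALSE], 2, stats::sd)
  structure(list(
    r_squared = obs$r2,
    betas = stats::setNames(obs$beta, colnames(Xm)),
    betas_std = stats::setNames(obs$beta[-1] * sds / stats::sd(y), names(X)),
    beta_pvalues = stats::setNames((1 + exceed_t) / (n_perm + 1), colnames(Xm)),
    model_pvalue = (1 + exceed_f) / (n_perm + 1),
    tstats = stats::setNames(obs$t, colnames(Xm)),
    n_perm = n_perm), class = "mmrr")
}

#' @export
print.mmrr <- function(x, ...) {
  cat("Multiple matrix regression with randomization\n")
  cat(sprintf("  R^2 = %.4f (model p = %.4g, %d permutations)\n",
              x$r_squared, x$model_pvalue, x$n_perm))
  for (nm in names(x$betas)[-1])
    cat(sprintf("  beta[%s] = %.4g (std %.3f, p = %.4g)\n", nm,
                x$betas[nm], x$betas_std[nm], x$beta_pvalues[nm]))
  invisible(x)
}

#' Commonality analysis for a two-predictor matrix regression
#'
#' Decomposes the full-model R^2 of Y ~ X1 + X2 into the variance unique to
#' each predictor (U_i = R^2_full - R^2 of the model without predictor i)
#' and the common component C = R^2_full - U1 - U2 contributed by their
#' collinearity; totals T_i = U_i + C.
#'
#' @param Y response distance matrix.
#' @param X1,X2 predictor distance matrices.
#' @return list with `r_squared`, `unique` (length 2), `common`, `total`,
#'   and `pct` (each component as a percentage of R^2).
#' @export
commonality_two <- function(Y, X1, X2) {
  y <- lower_vec(Y)
  x1 <- lower_vec(X1); x2 <- lower_vec(X2)
  r2 <- function(xm) {
    f <- stats::lm.fit(cbind(1, xm), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  degenerate <- abs(stats::cor(x1, x2)) > 1 - 1e-10
  if (degenerate) {
    # identical predictors: all explained variance is common
    r2_full <- r2(cbind(x1))
    u <- c(X1 = 0, X2 = 0)
    common <- r2_full
  } else {
    r2_full <- r2(cbind(x1, x2))
    u <- c(X1 = r2_full - r2(cbind(x2)), X2 = r2_full - r2(cbind(x1)))
    common <- r2_full - sum(u)
  }
  list(r_squared = r2_full, unique = u, common = common,
       total = u + common,
       pct = 100 * c(unique = u, common = common) / r2_full,
       degenerate = degenerate)
}

#' Rank covariates by simple Mantel correlation with genetic distance
#'
#' A transparent stand-in for machine-learning covariate ranking: each
#' covariate's singleton environmental distance matrix is correlated with
#' the genetic distance matrix and covariates are ranked by Mantel r.
#'
#' @param gen_dist genetic distance matrix (e.g. linearized F_ST).
#' @param covariates localities x covariates table.
#' @param n_top how many covariates to return.
#' @return data.frame with `covariate`, `mantel_r`, ordered decreasing,
#'   truncated to `n_top`.
#' @export
rank_covariates <- function(gen_dist, covariates, n_top = 3) {
  rs <- vapply(colnames(covariates), function(nm) {
    d <- environmental_distance(covariates, nm)
    stats::cor(lower_vec(gen_dist), lower_vec(d))
  }, numeric(1))
  out <- data.frame(covariate = names(rs), mantel_r = rs,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mantel_r), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n_top)
}
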