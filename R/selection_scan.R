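#' Standardize population allele frequencies
#'
#' z_lj = (p_lj - pbar_l) / sqrt(pbar_l (1 - pbar_l)) with pbar_l the
#' sample-size-weighted mean frequency of locus l. Loci monomorphic across
#' all populations are excluded (their standardization is undefined).
#'
#' @param pop_freqs L x J matrix of per-population frequencies.
#' @param pop_sizes allele-copy counts per population (length J, or L x J
#'   matrix); equal weights when omitted.
#' @return list with `z` (kept loci x J), `p_bar`, `kept` (logical length
#'   L marking the loci retained).
#' @export
standardized_freqs <- function(pop_freqs, pop_sizes = NULL) {
  L <- nrow(pop_freqs); J <- ncol(pop_freqs)
  if (is.null(pop_sizes)) pop_sizes <- rep(1, J)
  W <- if (is.matrix(pop_sizes)) pop_sizes
       else matrix(pop_sizes, L, J, byrow = TRUE)
  p_bar <- rowSums(pop_freqs * W) / rowSums(W)
  kept <- p_bar > 0 & p_bar < 1
  z <- (pop_freqs[kept, , drop = FALSE] - p_bar[kept]) /
    sqrt(p_bar[kept] * (1 - p_bar[kept]))
  list(z = z, p_bar = p_bar[kept], kept = kept)
}

#' Estimate the population covariance matrix of standardized frequencies
#'
#' omega = Z'Z / L with linear shrinkage toward its diagonal (weight
#' `shrink`), which guarantees invertibility even for near-duplicated
#' populations.
#'
#' @param z L x J standardized frequency matrix.
#' @param shrink shrinkage weight toward the diagonal.
#' @return J x J symmetric positive-definite matrix.
#' @export
estimate_omega <- function(z, shrink = 0.05) {
  L <- nrow(z); J <- ncol(z)
  if (L < J) stop("need at least as many loci as populations")
  omega <- crossprod(z) / L
  (1 - shrink) * omega + shrink * diag(diag(omega), J)
}

#' Structure-corrected per-locus differentiation statistic (XtX)
#'
#' The quadratic form z_l' omega^{-1} z_l: an F_ST-like statistic that
#' whitens out the population covariance structure, approximately
#' chi-squared with J degrees of freedom for neutral loci under the
#' Gaussian model.
#'
#' @param z L x J standardized frequency matrix.
#' @param omega J x J population covariance.
#' @return numeric vector of length L.
#' @export
xtx_stat <- function(z, omega) {
  rowSums((z %*% solve(omega)) * z)
}

# symmetric inverse square root via eigendecomposition
inv_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values <= 0)) stop("matrix is not positive-definite")
  e$vectors %*% diag(1 / sqrt(e$values), nrow(m)) %*% t(e$vectors)
}

#' Structure-corrected environmental association per locus
#'
#' Whitens both the locus's standardized frequency vector and the z-scored
#' covariate by omega^{-1/2} and returns their Pearson correlation: a
#' deterministic surrogate for a Bayes factor, monotone in association
#' strength and corrected for population structure.
#'
#' @param z L x J standardized frequency matrix.
#' @param omega J x J population covariance.
#' @param covariate covariate value per population (length J).
#' @param scaled z-score the covariate first (recommended).
#' @return numeric vector of per-locus correlations in [-1, 1].
#' @export
env_association <- function(z, omega, covariate, scaled = TRUE) {
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  x <- if (scaled) as.numeric(scale(covariate)) else covariate
  W <- inv_sqrt(omega)
  zw <- z %*% W
  xw <- drop(W %*% x)
  zc <- zw - rowMeans(zw)
  xc <- xw - mean(xw)
  drop(zc %*% xc) / (sqrt(rowSums(zc^2)) * sqrt(sum(xc^2)))
}

#' Calibrate outlier thresholds with pseudo-observed datasets (PODs)
#'
#' Simulates neutral loci under the fitted covariance model: locus mean
#' frequencies are resampled from the empirical locus-mean distribution,
#' standardized deviates are drawn multivariate-normal(0, omega),
#' frequencies are back-transformed, clamped to (0.001, 0.999) and
#' re-standardized through the same code path as real loci (so clamping
#' cannot bias the calibration). Thresholds are the 99% and 99.9% POD
#' quantiles of XtX and the 99.9% quantile of |association|.
#'
#' @param omega fitted population covariance.
#' @param freq_spectrum empirical locus mean frequencies to resample.
#' @param covariates optional named list / data.frame of per-population
#'   covariates for association thresholds.
#' @param n_pods number of neutral loci to simulate.
#' @param quantiles XtX quantile levels.
#' @param seed integer seed.
#' @return list with `xtx_99`, `xtx_999`, `assoc_999` (named by covariate),
#'   and the POD statistics (`pod_xtx`, `pod_assoc`).
#' @export
pod_calibrate <- function(omega, freq_spectrum, covariates = NULL,
                          n_pods = 100000, quantiles = c(0.99, 0.999),
                          seed = NULL) {
  if (n_pods < 1000) warning("fewer than 1000 PODs; quantiles unstable")
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(omega)
  p_bar <- sample(freq_spectrum, n_pods, replace = TRUE)
  ch <- chol(omega)
  z_raw <- matrix(stats::rnorm(n_pods * J), n_pods, J) %*% ch
  p <- p_bar + z_raw * sqrt(p_bar * (1 - p_bar))
  p <- pmin(pmax(p, 0.001), 0.999)
  sf <- standardized_freqs(p)
  pod_xtx <- xtx_stat(sf$z, omega)
  qx <- stats::quantile(pod_xtx, quantiles, names = FALSE)
  assoc_999 <- NULL; pod_assoc <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    pod_assoc <- vapply(covariates, function(x)
      env_association(sf$z, omega, x), numeric(nrow(sf$z)))
    assoc_999 <- apply(abs(pod_assoc), 2, stats::quantile, 0.999,
                       names = FALSE)
  }
  list(xtx_99 = qx[1], xtx_999 = qx[2], assoc_999 = assoc_999,
       pod_xtx = pod_xtx, pod_assoc = pod_assoc, n_pods = n_pods)
}

#' End-to-end outlier and genotype-environment association scan
#'
#' Aggregates called dosages to population allele frequencies, estimates
#' the population covariance omega, computes per-locus XtX and per-covariate
#' structure-corrected associations, calibrates thresholds with neutral
#' PODs, and flags outliers at a conservative (XtX above its 99% POD
#' quantile and some |association| above its 99.9% quantile) and a very
#' conservative (XtX above 99.9%) criterion.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @param membership locality per individual.
#' @param covariates localities x covariates table (rownames or order
#'   matching the localities appearing in `membership`).
#' @param n_pods POD count for calibration.
#' @param shrink omega shrinkage weight.
#' @param seed integer seed (drives the POD simulation).
#' @return An object of class `"selection_scan"`: list with `table` (per
#'   locus: site, xtx, assoc_<covariate>, outlier flags), `omega`,
#'   `thresholds`, `n_loci`. Supports `print()`.
#' @export
selection_scan <- function(dosage, membership, covariates,
                           n_pods = 100000, shrink = 0.05, seed = NULL) {
  af <- pop_allele_freq(dosage, membership)
  pops <- colnames(af$q)
  covariates <- as.data.frame(covariates)
  if (all(pops %in% rownames(covariates))) {
    covariates <- covariates[pops, , drop = FALSE]
  } else if (nrow(covariates) != length(pops)) {
    stop("covariates must have one row per locality")
  }
  sf <- standardized_freqs(af$q, af$m)
  omega <- estimate_omega(sf$z, shrink = shrink)
  xtx <- xtx_stat(sf$z, omega)
  assoc <- vapply(covariates, function(x)
    env_association(sf$z, omega, x), numeric(nrow(sf$z)))
  cal <- pod_calibrate(omega, sf$p_bar, covariates,
                       n_pods = n_pods, seed = seed)

  any_assoc <- apply(abs(assoc) >= matrix(cal$assoc_999, nrow(assoc),
                                          ncol(assoc), byrow = TRUE),
                     1, any)
  tab <- data.frame(site = rownames(sf$z), xtx = xtx,
                    stringsAsFactors = FALSE)
  for (nm in colnames(assoc)) tab[[paste0("assoc_", nm)]] <- assoc[, nm]
  tab$outlier_conservative <- xtx >= cal$xtx_99 & any_assoc
  tab$outlier_very_conservative <- xtx >= cal$xtx_999 & any_assoc
  tab$xtx_outlier_99 <- xtx >= cal$xtx_99
  tab$xtx_outlier_999 <- xtx >= cal$xtx_999

  structure(list(table = tab, omega = omega,
                 thresholds = list(xtx_99 = cal$xtx_99,
                                   xtx_999 = cal$xtx_999,
                                   assoc_999 = cal$assoc_999),
                 n_loci = nrow(sf$z), kept = sf$kept,
                 n_pods = n_pods, seed = seed),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("Structure-corrected outlier scan (whitened-correlation surrogate;\n")
  cat("thresholds calibrated on neutral pseudo-observed data)\n")
  cat(sprintf("  loci scanned           : %d\n", x$n_loci))
  cat(sprintf("  XtX thresholds (99/99.9%%): %.2f / %.2f\n",
              x$thresholds$xtx_99, x$thresholds$xtx_999))
  cat(sprintf("  conservative outliers  : %d (%.2f%%)\n",
              sum(x$table$outlier_conservative),
              100 * mean(x$table$outlier_conservative)))
  cat(sprintf("  very conservative      : %d (%.2f%%)\n",
              sum(x$table$outlier_very_conservative),
              100 * mean(x$table$outlier_very_conservative)))
  invisible(x)
}
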