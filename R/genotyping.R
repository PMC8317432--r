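#' Per-site sequencing error rate from third-allele reads
#'
#' The fraction of reads matching neither the reference nor the alternative
#' allele estimates half of the total sequencing error rate (the other half
#' flips reads between the two focal alleles and is invisible here). A
#' pseudocount-stabilized estimate is used so that sites with no observed
#' third-allele reads still receive a proper, non-zero error rate:
#' `epsilon = (1 + sum(other)) / (2 + sum(total))`, clamped to
#' `[1e-4, 0.1]`.
#'
#' @param ref,alt,other integer vectors of per-individual read counts at one
#'   site.
#' @return epsilon, a scalar in `[1e-4, 0.1]`; `NA` if the site has no reads.
#' @export
estimate_site_error <- function(ref, alt, other) {
  tot <- sum(ref) + sum(alt) + sum(other)
  if (tot == 0) return(NA_real_)
  eps <- (1 + sum(other)) / (2 + tot)
  min(max(eps, 1e-4), 0.1)
}

#' Genotype log-likelihoods for a tetraploid site
#'
#' For dosage g in 0..4 the probability that a read reports the alternative
#' allele is `h_g = (g/4) (1 - epsilon) + (1 - g/4) epsilon`; the five
#' log-likelihoods are Binomial(depth, h_g) evaluated at the alternative
#' read count.
#'
#' @param a alternative-allele read count (vector ok).
#' @param d total ref+alt depth (vector ok, recycled against `a`).
#' @param epsilon per-site error rate.
#' @return If `a` is scalar, a length-5 numeric vector; otherwise a
#'   `length(a)` x 5 matrix of log-likelihoods (columns g = 0..4).
#' @export
genotype_loglik <- function(a, d, epsilon) {
  if (any(a > d)) stop("alt count exceeds depth")
  h <- (0:4) / 4 * (1 - epsilon) + (1 - (0:4) / 4) * epsilon
  ll <- vapply(h, function(hg) stats::dbinom(a, d, hg, log = TRUE),
               numeric(length(a)))
  if (length(a) == 1) as.numeric(ll) else ll
}

#' EM estimate of the site allele frequency under a tetrasomic prior
#'
#' Starting from the raw read fraction, iterates an EM in which each
#' individual's dosage posterior combines its genotype likelihoods with a
#' Binomial(4, q) population prior (random tetrasomic mating), and q is
#' re-estimated as the posterior mean dosage over 4n. This is the
#' "empirical Bayes" refinement: the prior is learned from the cohort
#' rather than fixed flat.
#'
#' @param loglik n x 5 matrix of genotype log-likelihoods (missing
#'   individuals as rows of NA).
#' @param q_init optional starting frequency; defaults to 0.5 when not
#'   supplied by the caller.
#' @param tol convergence tolerance on |delta q|.
#' @param max_iter iteration cap.
#' @return A list with `q_hat`, `posterior` (n x 5, rows sum to 1),
#'   `n_iter`, and `loglik_trace` (observed-data log-likelihood per
#'   iteration, non-decreasing).
#' @export
em_site_frequency <- function(loglik, q_init = 0.5, tol = 1e-6,
                              max_iter = 100) {
  ok <- stats::complete.cases(loglik)
  if (!any(ok)) stop("site has no individuals with data")
  ll <- loglik[ok, , drop = FALSE]
  n <- nrow(ll)
  q <- min(max(q_init, 1e-4), 1 - 1e-4)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- stats::dbinom(0:4, 4, q, log = TRUE)
    w <- sweep(ll, 2, lp, "+")
    mx <- apply(w, 1, max)
    pw <- exp(w - mx)
    rs <- rowSums(pw)
    post <- pw / rs
    trace <- c(trace, sum(mx + log(rs)))
    q_new <- sum(post %*% (0:4)) / (4 * n)
    q_new <- min(max(q_new, 1e-6), 1 - 1e-6)
    if (abs(q_new - q) < tol) { q <- q_new; break }
    q <- q_new
  }
  # final posterior at the converged q
  lp <- stats::dbinom(0:4, 4, q, log = TRUE)
  w <- sweep(loglik, 2, lp, "+")
  mx <- apply(w, 1, max)
  pw <- exp(w - mx)
  post_all <- pw / rowSums(pw)
  list(q_hat = q, posterior = post_all, n_iter = it, loglik_trace = trace)
}

#' Call tetraploid genotypes from read counts
#'
#' Empirical-Bayes dosage calling: per site, a sequencing error rate is
#' estimated from third-allele reads, genotype likelihoods are computed for
#' dosages 0..4, an EM learns the site allele frequency under a tetrasomic
#' Binomial(4, q) prior, and each individual's dosage is the posterior
#' argmax (ties broken toward the dosage nearest 4q). Cells with depth below
#' `min_depth` are missing. Sites are dropped when their missing fraction
#' exceeds `max_missing`, their minor allele frequency falls below
#' `maf_min`, or fewer than `min_carriers` called individuals carry each
#' allele (a singleton-noise guard standing in for an upstream site-quality
#' filter).
#'
#' @param reads a `"read_counts"` object (matrices `ref`, `alt`, `other`).
#' @param min_depth minimum ref+alt+other depth for a called cell.
#' @param max_missing maximum tolerated fraction of missing individuals per
#'   site.
#' @param maf_min minimum minor allele frequency (EM estimate).
#' @param min_carriers minimum number of called individuals carrying each
#'   allele at non-zero dosage.
#' @return An object of class `"tetra_genotypes"`: list with `dosage`
#'   (individuals x retained sites, NA = missing), `posterior_max`,
#'   `site_info` (data.frame: site, epsilon, q_hat, maf, n_called), and the
#'   filter parameters. Supports `print()` and `summary()`.
#' @export
call_genotypes <- function(reads, min_depth = 5, max_missing = 0.10,
                           maf_min = 0.05, min_carriers = 2) {
  ref <- reads$ref; alt <- reads$alt; other <- reads$other
  n <- nrow(ref); L <- ncol(ref)
  depth <- ref + alt + other
  callable <- depth >= min_depth

  eps <- vapply(seq_len(L), function(l)
    estimate_site_error(ref[, l], alt[, l], other[, l]), numeric(1))

  dosage <- matrix(NA_integer_, n, L, dimnames = dimnames(ref))
  postmax <- matrix(NA_real_, n, L, dimnames = dimnames(ref))
  q_hat <- rep(NA_real_, L)
  n_called <- integer(L)

  # vectorized across sites: 5 loglik layers (n x L each)
  d_ra <- ref + alt
  ll <- lapply(0:4, function(g) {
    h <- outer(rep(1, n), g / 4 * (1 - eps) + (1 - g / 4) * eps)
    out <- stats::dbinom(alt, d_ra, h, log = TRUE)
    out[!callable] <- NA_real_
    out
  })
  usable <- callable & !is.na(eps)[col(callable)]

  # EM jointly over all sites (each site has its own q)
  q <- colSums(alt * usable) / pmax(colSums(d_ra * usable), 1)
  q <- pmin(pmax(q, 1e-4), 1 - 1e-4)
  alive <- colSums(usable) > 0
  for (it in 1:100) {
    w <- lapply(0:4, function(g)
      ll[[g + 1]] + rep(stats::dbinom(g, 4, q, log = TRUE), each = n))
    mx <- pmax(w[[1]], w[[2]], w[[3]], w[[4]], w[[5]], na.rm = TRUE)
    pw <- lapply(w, function(x) exp(x - mx))
    tot <- Reduce(`+`, lapply(pw, function(x) ifelse(is.na(x), 0, x)))
    num <- Reduce(`+`, lapply(1:4, function(g)
      ifelse(is.na(pw[[g + 1]]), 0, g * pw[[g + 1]])))
    nc <- colSums(usable)
    q_new <- ifelse(alive, colSums(num / pmax(tot, 1e-300) * usable) /
                      (4 * pmax(nc, 1)), q)
    q_new <- pmin(pmax(q_new, 1e-6), 1 - 1e-6)
    if (max(abs(q_new - q)) < 1e-6) { q <- q_new; break }
    q <- q_new
  }
  q_hat <- q

  # posterior argmax with deterministic tie-break toward 4q
  w <- lapply(0:4, function(g)
    ll[[g + 1]] + rep(stats::dbinom(g, 4, q, log = TRUE), each = n))
  W <- array(unlist(w), dim = c(n, L, 5))
  mx <- pmax(w[[1]], w[[2]], w[[3]], w[[4]], w[[5]], na.rm = TRUE)
  tot <- Reduce(`+`, lapply(w, function(x) {
    e <- exp(x - mx); ifelse(is.na(e), 0, e)
  }))
  for (l in which(alive)) {
    cells <- which(usable[, l])
    if (!length(cells)) next
    pm <- exp(W[cells, l, , drop = FALSE][, 1, ] -
              matrix(mx[cells, l], length(cells), 5)) /
          matrix(tot[cells, l], length(cells), 5)
    pm <- matrix(pm, length(cells), 5)
    best <- max.col(pm, ties.method = "first")
    # resolve near-ties (within 1e-12) toward the dosage nearest 4q
    top <- pm[cbind(seq_along(cells), best)]
    tied <- abs(pm - top) < 1e-12
    target <- 4 * q[l]
    dist <- abs(matrix(0:4, length(cells), 5, byrow = TRUE) - target)
    dist[!tied] <- Inf
    pick <- max.col(-dist, ties.method = "first")
    dosage[cells, l] <- pick - 1L
    postmax[cells, l] <- pm[cbind(seq_along(cells), pick)]
    n_called[l] <- length(cells)
  }

  maf <- pmin(q_hat, 1 - q_hat)
  carriers_alt <- colSums(dosage > 0, na.rm = TRUE)
  carriers_ref <- colSums(dosage < 4, na.rm = TRUE)
  keep <- alive &
    (n - n_called) / n <= max_missing &
    maf >= maf_min &
    carriers_alt >= min_carriers & carriers_ref >= min_carriers

  if (!any(keep))
    stop(sprintf(
      "all %d sites filtered (missingness removed %d, maf %d, carriers %d)",
      L, sum((n - n_called) / n > max_missing), sum(maf < maf_min, na.rm = TRUE),
      sum(carriers_alt < min_carriers | carriers_ref < min_carriers)))

  site_info <- data.frame(
    site = colnames(ref)[keep], epsilon = eps[keep], q_hat = q_hat[keep],
    maf = maf[keep], n_called = n_called[keep],
    stringsAsFactors = FALSE)

  structure(list(dosage = dosage[, keep, drop = FALSE],
                 posterior_max = postmax[, keep, drop = FALSE],
                 site_info = site_info,
                 n_sites_input = L,
                 params = list(min_depth = min_depth,
                               max_missing = max_missing,
                               maf_min = maf_min,
                               min_carriers = min_carriers)),
            class = "tetra_genotypes")
}

#' @export
print.tetra_genotypes <- function(x, ...) {
  cat("Tetraploid genotype calls\n")
  cat(sprintf("  individuals : %d\n", nrow(x$dosage)))
  cat(sprintf("  sites       : %d retained of %d input\n",
              ncol(x$dosage), x$n_sites_input))
  cat(sprintf("  missing     : %.2f%% of retained cells\n",
              100 * mean(is.na(x$dosage))))
  cat(sprintf("  filters     : min_depth=%d, max_missing=%.2f, maf>=%.3g\n",
              x$params$min_depth, x$params$max_missing, x$params$maf_min))
  invisible(x)
}

#' @export
summary.tetra_genotypes <- function(object, ...) {
  dos <- table(factor(object$dosage, levels = 0:4))
  out <- list(
    n_individuals = nrow(object$dosage),
    n_sites = ncol(object$dosage),
    dosage_proportions = dos / sum(dos),
    mean_epsilon = mean(object$site_info$epsilon),
    mean_posterior_max = mean(object$posterior_max, na.rm = TRUE))
  class(out) <- "summary.tetra_genotypes"
  out
}

#' @export
print.summary.tetra_genotypes <- function(x, ...) {
  cat(sprintf("%d individuals x %d sites\n", x$n_individuals, x$n_sites))
  cat("dosage class proportions (0..4):\n")
  print(round(as.numeric(x$dosage_proportions), 4))
  cat(sprintf("mean per-site error rate: %.4g\n", x$mean_epsilon))
  cat(sprintf("mean max posterior: %.3f\n", x$mean_posterior_max))
  invisible(x)
}

#' Write genotype calls to disk
#'
#' Emits a dosage TSV (individuals x sites), a site-info TSV, and a
#' ploidy-4 VCF whose GT strings encode the called dosages.
#'
#' @param calls a `"tetra_genotypes"` object.
#' @param reads the `"read_counts"` object the calls came from (for AD/DP).
#' @param out_dir output directory.
#' @return Invisibly, the files written.
#' @export
write_genotypes <- function(calls, reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(dosage = file.path(out_dir, "dosage.tsv"),
             sites = file.path(out_dir, "site_info.tsv"),
             vcf = file.path(out_dir, "genotypes.vcf"))
  write_matrix_tsv(calls$dosage, files["dosage"], id_col = "individual")
  utils::write.table(calls$site_info, files["sites"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  keep <- calls$site_info$site
  sub <- structure(list(ref = reads$ref[, keep, drop = FALSE],
                        alt = reads$alt[, keep, drop = FALSE],
                        other = reads$other[, keep, drop = FALSE]),
                   class = "read_counts")
  write_read_vcf(sub, files["vcf"], gt = calls$dosage)
  invisible(files)
}
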