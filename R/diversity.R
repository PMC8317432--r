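#' Per-site, per-locality allele frequencies and allele-copy counts
#'
#' For tetraploids each called individual contributes four allele copies:
#' m = 4 n_called and q = sum(dosage) / m.
#'
#' @param dosage individuals x sites matrix in 0..4 (NA = missing), or a
#'   `"tetra_genotypes"` object.
#' @param membership character/factor of locality per individual.
#' @return A list with matrices `q` (sites x localities, NA where a
#'   locality has no called individual) and `m` (allele copies).
#' @export
pop_allele_freq <- function(dosage, membership) {
  if (inherits(dosage, "tetra_genotypes")) dosage <- dosage$dosage
  membership <- as.character(membership)
  pops <- unique(membership)
  L <- ncol(dosage)
  q <- m <- matrix(NA_real_, L, length(pops),
                   dimnames = list(colnames(dosage), pops))
  for (p in pops) {
    sub <- dosage[membership == p, , drop = FALSE]
    nc <- colSums(!is.na(sub))
    m[, p] <- 4 * nc
    q[, p] <- ifelse(nc > 0, colSums(sub, na.rm = TRUE) / (4 * nc), NA)
  }
  list(q = q, m = m)
}

#' Unbiased gene diversity at one or more sites
#'
#' Hs = (m / (m - 1)) * 2 q (1 - q), the small-sample-corrected expected
#' heterozygosity for m sampled allele copies. Sites with m < 2 return NA.
#'
#' @param q allele frequency (vectorized).
#' @param m allele-copy count (vectorized).
#' @return Hs, same shape as `q`.
#' @export
gene_diversity <- function(q, m) {
  ifelse(!is.na(m) & m >= 2, m / (m - 1) * 2 * q * (1 - q), NA_real_)
}

#' Per-locality diversity summary
#'
#' Computes, per locality: He (mean unbiased gene diversity over retained
#' SNPs, monomorphic-within-locality SNPs contributing zero), Ho (mean
#' within-individual heterozygosity, where a tetraploid of dosage g is
#' heterozygous at g(4-g)/6 of its C(4,2) copy-pairs), F_IS = 1 - Ho/He,
#' nucleotide diversity pi = sum of site Hs over the total callable bases
#' (per-base average pairwise difference; an order of magnitude below He
#' when SNPs are sparse along the loci), and small-sample-corrected private
#' allele counts.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @param membership locality per individual.
#' @param total_callable_bp total callable bases for the pi denominator;
#'   defaults to `n_snps * locus_length_bp` (one SNP per RAD locus).
#' @param locus_length_bp RAD locus length used for the default
#'   normalization (94 bp).
#' @param region optional named vector mapping locality -> region label,
#'   carried through to the output.
#' @return data.frame with one row per locality: `locality`, `region`,
#'   `n_individuals`, `pi`, `he`, `ho`, `fis`, `private_alleles`
#'   (unrounded, small-sample corrected) and `private_alleles_raw`.
#' @export
diversity_summary <- function(dosage, membership, total_callable_bp = NULL,
                              locus_length_bp = 94, region = NULL) {
  if (inherits(dosage, "tetra_genotypes")) dosage <- dosage$dosage
  membership <- as.character(membership)
  af <- pop_allele_freq(dosage, membership)
  L <- ncol(dosage)
  if (is.null(total_callable_bp)) total_callable_bp <- L * locus_length_bp
  if (total_callable_bp < L)
    stop("total_callable_bp must be at least the number of SNP sites")
  pops <- colnames(af$q)

  hs <- gene_diversity(af$q, af$m)      # sites x localities
  priv <- private_alleles(dosage, membership)

  out <- lapply(pops, function(p) {
    sub <- dosage[membership == p, , drop = FALSE]
    he <- mean(hs[, p], na.rm = TRUE)
    ho <- mean(sub * (4 - sub) / 6, na.rm = TRUE)
    data.frame(
      locality = p,
      region = if (is.null(region)) NA_character_ else unname(region[p]),
      n_individuals = sum(membership == p),
      pi = sum(hs[, p], na.rm = TRUE) / total_callable_bp,
      he = he, ho = ho,
      fis = if (he > 0) 1 - ho / he else NA_real_,
      private_alleles = priv$corrected[p],
      private_alleles_raw = priv$raw[p],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Private allele counts with small-sample correction
#'
#' An allele (reference or alternative) at a site is private to a group when
#' it is carried (dosage evidence > 0) in that group and in no other. Raw
#' counts are corrected by (n + 1)/n where n is the number of individuals
#' in the group.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @param membership group per individual (any partition: locality or
#'   cluster).
#' @return list with named vectors `raw` and `corrected`.
#' @export
private_alleles <- function(dosage, membership) {
  if (inherits(dosage, "tetra_genotypes")) dosage <- dosage$dosage
  membership <- as.character(membership)
  groups <- unique(membership)
  # carriage of alt / ref allele per group x site
  has_alt <- t(vapply(groups, function(g)
    colSums(dosage[membership == g, , drop = FALSE] > 0, na.rm = TRUE) > 0,
    logical(ncol(dosage))))
  has_ref <- t(vapply(groups, function(g)
    colSums(dosage[membership == g, , drop = FALSE] < 4, na.rm = TRUE) > 0,
    logical(ncol(dosage))))
  raw <- vapply(seq_along(groups), function(i) {
    alt_priv <- has_alt[i, ] & colSums(has_alt[-i, , drop = FALSE]) == 0
    ref_priv <- has_ref[i, ] & colSums(has_ref[-i, , drop = FALSE]) == 0
    sum(alt_priv) + sum(ref_priv)
  }, numeric(1))
  n <- as.numeric(table(membership)[groups])
  names(raw) <- groups
  list(raw = raw, corrected = raw * (n + 1) / n)
}

#' Pairwise F_ST matrix between localities
#'
#' Nei-style F_ST per pair as a ratio of sums over sites:
#' per site H_T = 2 qbar (1 - qbar) with qbar the unweighted mean of the two
#' locality frequencies, H_S the mean of the two unbiased within-locality
#' gene diversities; F_ST = sum(H_T - H_S) / sum(H_T). Negative totals are
#' clamped to zero. The ratio-of-sums form avoids instability at
#' low-diversity sites.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @param membership locality per individual.
#' @return symmetric localities x localities matrix, zero diagonal, values
#'   in [0, 1]; NA where a pair shares no polymorphic site.
#' @export
pairwise_fst <- function(dosage, membership) {
  af <- pop_allele_freq(dosage, membership)
  fst_from_freqs(af$q, af$m)
}

#' Pairwise F_ST from per-locality frequencies
#'
#' Workhorse behind [pairwise_fst()], also usable directly on true
#' simulated frequencies (with `m = Inf` for the drift-free limit).
#'
#' @param q sites x localities frequency matrix.
#' @param m matching allele-copy counts; `Inf` (default) disables the
#'   small-sample correction.
#' @return symmetric F_ST matrix.
#' @export
fst_from_freqs <- function(q, m = Inf) {
  J <- ncol(q)
  if (J < 2) stop("need at least 2 localities")
  if (length(m) == 1) m <- matrix(m, nrow(q), J)
  hs <- ifelse(is.finite(m), gene_diversity(q, m), 2 * q * (1 - q))
  fst <- matrix(0, J, J, dimnames = list(colnames(q), colnames(q)))
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    ok <- !is.na(q[, i]) & !is.na(q[, j])
    qbar <- (q[ok, i] + q[ok, j]) / 2
    ht <- 2 * qbar * (1 - qbar)
    hsm <- (hs[ok, i] + hs[ok, j]) / 2
    s_ht <- sum(ht)
    fst[i, j] <- fst[j, i] <-
      if (s_ht > 0) max(0, (s_ht - sum(hsm)) / s_ht) else NA_real_
  }
  fst
}

#' Regional mean and standard error of per-locality statistics
#'
#' @param values named numeric vector of per-locality values.
#' @param regions region label per locality (same order).
#' @return data.frame with `region`, `k` (localities), `mean`, `se`
#'   (sample SD / sqrt(k); NA when k < 2).
#' @export
region_summary <- function(values, regions) {
  regions <- as.character(regions)
  out <- lapply(unique(regions), function(r) {
    v <- values[regions == r]
    data.frame(region = r, k = length(v), mean = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
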