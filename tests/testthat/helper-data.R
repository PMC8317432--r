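# shared fixture builders (all generated in code, seeded)

# read counts for one site as a read_counts object
one_site_reads <- function(ref, alt, other = rep(0L, length(ref))) {
  n <- length(ref)
  dn <- list(sprintf("ind_%02d", seq_len(n)), "site_00001")
  structure(list(ref = matrix(as.integer(ref), n, 1, dimnames = dn),
                 alt = matrix(as.integer(alt), n, 1, dimnames = dn),
                 other = matrix(as.integer(other), n, 1, dimnames = dn)),
            class = "read_counts")
}

# two well-diverged populations of tetrasomic genotypes with labels
two_pop_dosage <- function(n_per_pop = 30, n_loci = 400, shift = 3,
                           seed = 42) {
  set.seed(seed)
  p0 <- runif(n_loci, 0.1, 0.9)
  eta <- qlogis(p0)
  p1 <- plogis(eta - shift / 2)
  p2 <- plogis(eta + shift / 2)
  g1 <- matrix(rbinom(n_per_pop * n_loci, 4, rep(p1, each = n_per_pop)),
               n_per_pop, n_loci)
  g2 <- matrix(rbinom(n_per_pop * n_loci, 4, rep(p2, each = n_per_pop)),
               n_per_pop, n_loci)
  dosage <- rbind(g1, g2)
  dimnames(dosage) <- list(
    c(sprintf("A_%02d", 1:n_per_pop), sprintf("B_%02d", 1:n_per_pop)),
    sprintf("site_%04d", seq_len(n_loci)))
  list(dosage = dosage,
       membership = rep(c("A", "B"), each = n_per_pop))
}

# symmetric random distance-like matrix with zero diagonal
random_dist <- function(J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, J, J)
  m[lower.tri(m)] <- runif(J * (J - 1) / 2)
  m + t(m)
}
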