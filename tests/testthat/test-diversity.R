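test_that("population allele frequencies match a brute-force recount", {
  d <- matrix(c(1L, 3L, NA, 2L), 2, 2,
              dimnames = list(c("a1", "a2"), c("s1", "s2")))
  af <- pop_allele_freq(d, c("P", "P"))
  expect_equal(af$q["s1", "P"], 0.5)
  expect_equal(af$m["s1", "P"], 8)
  # s2: one called individual with dosage 2
  expect_equal(af$q["s2", "P"], 0.5)
  expect_equal(af$m["s2", "P"], 4)

  allmiss <- matrix(NA_integer_, 3, 1, dimnames = list(NULL, "s"))
  expect_true(is.na(pop_allele_freq(allmiss, rep("P", 3))$q[1, 1]))

  # randomized oracle
  set.seed(401)
  for (k in 1:5) {
    g <- matrix(sample(c(0:4, NA), 60, replace = TRUE), 6, 10,
                dimnames = list(NULL, sprintf("s%02d", 1:10)))
    mem <- sample(c("X", "Y"), 6, replace = TRUE)
    if (length(unique(mem)) < 2) next
    af <- pop_allele_freq(g, mem)
    for (p in c("X", "Y")) for (l in 1:10) {
      v <- g[mem == p, l]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        expect_true(is.na(af$q[l, p]))
      } else {
        expect_equal(af$q[l, p], sum(v) / (4 * length(v)))
      }
    }
  }
})

test_that("unbiased gene diversity follows its closed form", {
  expect_equal(gene_diversity(0.5, 8), 8 / 7 * 0.5)
  expect_equal(gene_diversity(0, 8), 0)
  expect_equal(gene_diversity(0.5, 1e9), 0.5, tolerance = 1e-8)
  expect_true(is.na(gene_diversity(0.5, 1)))
})

test_that("nucleotide diversity normalizes gene diversity per callable base", {
  # one SNP of Hs = 8/7 * 0.5 in a 94-bp locus
  d <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  div <- diversity_summary(d, c("P", "P"), total_callable_bp = 94)
  expect_equal(div$pi, (8 / 7 * 0.5) / 94)
  expect_equal(div$he, 8 / 7 * 0.5)
  # internal identity: pi * bp / n_snps equals mean unbiased Hs
  expect_equal(div$pi * 94 / 1, div$he)
  expect_error(diversity_summary(d, c("P", "P"), total_callable_bp = 0),
               "total_callable_bp")
})

test_that("pi from called frequencies is close to the truth-based oracle", {
  truth <- simulate_dataset(n_localities = 6, n_per_pop = 9, n_loci = 2000,
                            seed = 402)
  div <- diversity_summary(truth$dosage, truth$membership,
                           locus_length_bp = 94)
  # oracle: uncorrected heterozygosity from the true frequencies
  pi_true <- colSums(2 * truth$freq * (1 - truth$freq)) / (2000 * 94)
  expect_equal(unname(div$pi[match(colnames(truth$freq), div$locality)]),
               unname(pi_true), tolerance = 0.05)
})

test_that("observed heterozygosity and F_IS behave under tetrasomic HWE", {
  # closed forms: g(4-g)/6
  expect_equal(2 * (4 - 2) / 6, 2 / 3)
  # single panmictic tetrasomic population at HWE
  set.seed(403)
  p <- runif(5000, 0.05, 0.95)
  g <- matrix(rbinom(150 * 5000, 4, rep(p, each = 150)), 150, 5000,
              dimnames = list(NULL, sprintf("s%04d", 1:5000)))
  div <- diversity_summary(g, rep("P", 150))
  expect_lt(abs(div$fis), 0.02)
})

test_that("pairwise F_ST has its structural properties and matches an oracle", {
  tp <- two_pop_dosage(n_per_pop = 40, n_loci = 600, shift = 3, seed = 404)
  fst <- pairwise_fst(tp$dosage, tp$membership)
  expect_equal(fst, t(fst))
  expect_true(all(diag(fst) == 0))
  expect_true(all(fst >= 0 & fst <= 1))
  expect_gt(fst["A", "B"], 0.05)

  # independent per-site oracle (recomputed from scratch)
  gA <- tp$dosage[tp$membership == "A", ]
  gB <- tp$dosage[tp$membership == "B", ]
  qA <- colMeans(gA) / 4; qB <- colMeans(gB) / 4
  mA <- 4 * nrow(gA); mB <- 4 * nrow(gB)
  hsA <- mA / (mA - 1) * 2 * qA * (1 - qA)
  hsB <- mB / (mB - 1) * 2 * qB * (1 - qB)
  qb <- (qA + qB) / 2
  ht <- 2 * qb * (1 - qb)
  expect_equal(fst["A", "B"],
               max(0, (sum(ht) - sum((hsA + hsB) / 2)) / sum(ht)))

  # identical frequency vectors: F_ST = 0 (clamped unbiased estimate)
  same <- rbind(gA, gA)
  fst0 <- pairwise_fst(same, rep(c("A", "B"), each = nrow(gA)))
  expect_equal(fst0["A", "B"], 0)

  # fixed difference at every site approaches 1
  n <- 50
  fixed <- rbind(matrix(0L, n, 100), matrix(4L, n, 100))
  colnames(fixed) <- sprintf("s%03d", 1:100)
  fst1 <- pairwise_fst(fixed, rep(c("A", "B"), each = n))
  expect_gt(fst1["A", "B"], 0.99)
})

test_that("drift intensity lowers diversity and raises differentiation", {
  pops <- simulate_landscape(8, seed = 405)
  out <- lapply(c(0.3, 1.2), function(s) {
    tr <- simulate_allele_frequencies(pops, 1500, base_sd = s, seed = 406)
    tr <- draw_genotypes(tr, 9, seed = 407)
    list(he = mean(diversity_summary(tr$dosage, tr$membership)$he),
         fst = mean(fst_from_freqs(tr$freq)[upper.tri(diag(8))]))
  })
  expect_gt(out[[1]]$he, out[[2]]$he)
  expect_lt(out[[1]]$fst, out[[2]]$fst)
})

test_that("private alleles are counted exactly and corrected by (n+1)/n", {
  # constructed: alt allele at sites 1-2 only in group G1 (9 individuals)
  g <- matrix(0L, 12, 5, dimnames = list(NULL, sprintf("s%d", 1:5)))
  g[1, 1] <- 1L; g[2, 2] <- 2L     # two G1-private alt alleles
  g[1:12, 3] <- 1L                 # shared alt
  mem <- rep(c("G1", "G2"), c(9, 3))
  pa <- private_alleles(g, mem)
  expect_equal(unname(pa$raw["G1"]), 2)
  expect_equal(unname(pa$corrected["G1"]), 2 * 10 / 9)

  # brute-force oracle on random matrices
  set.seed(408)
  for (k in 1:5) {
    gg <- matrix(sample(0:4, 80, replace = TRUE, prob = c(8, 1, 1, 1, 2)),
                 8, 10)
    mm <- rep(c("X", "Y"), each = 4)
    pa <- private_alleles(gg, mm)
    for (grp in c("X", "Y")) {
      own <- gg[mm == grp, , drop = FALSE]
      oth <- gg[mm != grp, , drop = FALSE]
      raw <- sum(colSums(own > 0) > 0 & colSums(oth > 0) == 0) +
             sum(colSums(own < 4) > 0 & colSums(oth < 4) == 0)
      expect_equal(unname(pa$raw[grp]), raw)
    }
  }
})

test_that("regional aggregation reproduces published per-locality summaries", {
  tab <- alkanna_diversity()
  tinct <- tab[tab$species == "A. tinctoria", ]
  rs_he <- region_summary(tinct$he, tinct$group)
  expect_equal(rs_he$mean[rs_he$region == "Southern-Central"], 0.0996,
               tolerance = 1e-4)
  expect_equal(rs_he$mean[rs_he$region == "Northern"], 0.121,
               tolerance = 1e-3)
  # constant input has zero standard error
  rs0 <- region_summary(rep(0.1, 4), rep("R", 4))
  expect_equal(rs0$se, 0)
  # singleton region: SE undefined
  rs1 <- region_summary(c(1, 2), c("A", "B"))
  expect_true(all(is.na(rs1$se)))
})
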