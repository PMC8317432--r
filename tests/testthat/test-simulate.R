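test_that("landscape placement and covariate gradient behave as constructed", {
  pops <- simulate_landscape(16, extent_km = 500, n_covariates = 3, seed = 1)
  expect_equal(nrow(pops), 16)
  expect_false(anyDuplicated(pops[, c("lat", "lon")]) > 0)
  expect_named(pops, c("locality", "region", "lat", "lon",
                       "BIO12", "BIO18", "BIO19"))
  # covariates follow the latitudinal gradient up to noise
  expect_gt(cor(pops$lat, pops$BIO12), 0.5)

  # no-noise limit: covariate is an exact linear function of latitude
  quiet <- simulate_landscape(12, covariate_sd = 0, seed = 2)
  expect_equal(cor(quiet$lat, quiet$BIO12), 1.0)

  two <- simulate_landscape(2, seed = 3)
  d <- geographic_distance(two)
  expect_equal(dim(d), c(2, 2))
  expect_gt(d[1, 2], 0)

  expect_error(simulate_landscape(1), "n_localities")
})

test_that("allele-frequency field shows distance decay and clean IBE control", {
  pops <- simulate_landscape(16, seed = 5)
  truth <- simulate_allele_frequencies(pops, 2000, base_sd = 0.5,
                                       ibd_range = 200, seed = 5)
  expect_true(all(truth$freq > 0 & truth$freq < 1))

  # between-population logit-frequency correlation decays with distance
  eta <- qlogis(truth$freq)
  d <- geographic_distance(pops)
  cc <- cor(eta)
  pair <- which(upper.tri(d), arr.ind = TRUE)
  expect_lt(cor(d[pair], cc[pair], method = "spearman"), -0.8)

  # near-zero range: populations essentially independent given the locus mean
  ind <- simulate_allele_frequencies(pops, 2000, base_sd = 0.5,
                                     ibd_range = 1e-9, seed = 6)
  eta_c <- t(scale(t(qlogis(ind$freq)), scale = FALSE))  # remove locus mean
  cc_i <- cor(eta_c)
  expect_lt(mean(abs(cc_i[upper.tri(cc_i)])), 0.1)

  expect_error(simulate_allele_frequencies(pops, 10, base_sd = 0), "base_sd")
  expect_error(simulate_allele_frequencies(pops, 10, ibd_range = 0),
               "ibd_range")
  expect_error(simulate_allele_frequencies(pops, 10, n_adaptive = 11),
               "n_adaptive")
})

test_that("zero effect size leaves adaptive loci indistinguishable from neutral", {
  pops <- simulate_landscape(16, seed = 7)
  truth <- simulate_allele_frequencies(pops, 5000, n_adaptive = 250,
                                       effect_size = 0, seed = 7)
  z_env <- as.numeric(scale(pops$BIO12))
  r <- apply(qlogis(truth$freq), 1, cor, y = z_env)
  tt <- t.test(r[truth$adaptive], r[!truth$adaptive])
  expect_gt(tt$p.value, 0.01)
})

test_that("true-frequency F_ST increases across distance classes under IBD", {
  pops <- simulate_landscape(16, seed = 8)
  truth <- simulate_allele_frequencies(pops, 5000, base_sd = 0.5,
                                       ibd_range = 200, seed = 8)
  fst <- fst_from_freqs(truth$freq)
  d <- geographic_distance(pops)
  up <- upper.tri(d)
  cls <- cut(d[up], quantile(d[up], seq(0, 1, 0.25)), include.lowest = TRUE)
  means <- tapply(fst[up], cls, mean)
  expect_true(all(diff(means) > 0))
})

test_that("tetrasomic dosage draws match Binomial(4, p)", {
  pops <- simulate_landscape(2, seed = 9)
  for (p in c(0.2, 0.5)) {
    truth <- list(freq = matrix(p, 1, 2,
                                dimnames = list("s1", pops$locality)),
                  pops = pops)
    class(truth) <- "sim_truth"
    g <- draw_genotypes(truth, n_per_pop = 50000, mode = "tetrasomic",
                        seed = 10)$dosage
    obs <- table(factor(g, levels = 0:4))
    gof <- chisq.test(obs, p = dbinom(0:4, 4, p))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("disomic draws interpolate between tetrasomic and fixed heterozygosity", {
  pops <- simulate_landscape(2, seed = 11)
  truth <- structure(list(freq = matrix(0.5, 1, 2,
                                        dimnames = list("s1", pops$locality)),
                          pops = pops), class = "sim_truth")
  # full subgenome divergence at p = 0.5: every individual is duplex
  fixed <- draw_genotypes(truth, 1000, mode = "disomic",
                          subgenome_divergence = 1, seed = 12)$dosage
  expect_true(all(fixed == 2))

  # delta = 0 is distributionally identical to tetrasomic
  d0 <- draw_genotypes(truth, 50000, mode = "disomic",
                       subgenome_divergence = 0, seed = 13)$dosage
  tet <- draw_genotypes(truth, 50000, mode = "tetrasomic", seed = 14)$dosage
  tab <- rbind(table(factor(d0, levels = 0:4)),
               table(factor(tet, levels = 0:4)))
  expect_gt(chisq.test(tab)$p.value, 0.01)

  expect_error(draw_genotypes(truth, 5, mode = "hexasomic"))
})

test_that("read model honours depth, error split, and determinism", {
  set.seed(21)
  dosage <- matrix(sample(0:4, 1e5, replace = TRUE), 500, 200)
  reads <- simulate_read_counts(dosage, mean_depth = 16,
                                depth_dispersion = 8, seed = 22)
  depth <- reads$ref + reads$alt + reads$other
  expect_lt(abs(mean(depth) - 16) / 16, 0.02)
  # overdispersed: SD well above the Poisson sqrt(16) = 4
  expect_gt(sd(depth), 5)

  g0 <- matrix(0L, 100, 100)
  clean <- simulate_read_counts(g0, error_rate = 0, seed = 23)
  expect_true(all(clean$alt == 0) && all(clean$other == 0))

  noisy <- simulate_read_counts(matrix(0L, 200, 500), mean_depth = 30,
                                error_rate = 0.02, seed = 24)
  tot <- sum(noisy$ref + noisy$alt + noisy$other)
  expect_equal(sum(noisy$alt) / tot, 0.01 * (1 - 0.01), tolerance = 0.05)
  expect_equal(sum(noisy$other) / tot, 0.01, tolerance = 0.05)

  again <- simulate_read_counts(dosage, mean_depth = 16,
                                depth_dispersion = 8, seed = 22)
  expect_identical(reads, again)

  expect_error(simulate_read_counts(g0, error_rate = 0.5), "error_rate")
  expect_error(simulate_read_counts(matrix(7L, 2, 2)), "0..4")
})

test_that("whole-dataset simulation is reproducible under one seed", {
  a <- simulate_dataset(n_localities = 4, n_per_pop = 3, n_loci = 50,
                        seed = 31)
  b <- simulate_dataset(n_localities = 4, n_per_pop = 3, n_loci = 50,
                        seed = 31)
  expect_identical(a$freq, b$freq)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$reads, b$reads)
})
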