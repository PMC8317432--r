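test_that("haversine distances match closed forms and the triangle inequality", {
  pops <- data.frame(locality = c("a", "b"), region = "r",
                     lat = c(0, 0), lon = c(0, 1))
  d <- geographic_distance(pops)
  expect_equal(d["a", "b"], 111.19, tolerance = 0.1 / 111.19)

  same <- data.frame(locality = c("a", "b"), region = "r",
                     lat = c(10, 10), lon = c(5, 5))
  expect_equal(geographic_distance(same)["a", "b"], 0)
  expect_error(geographic_distance(same, log_transform = TRUE), "log")

  set.seed(601)
  tri <- data.frame(locality = c("a", "b", "c"), region = "r",
                    lat = runif(3, -60, 60), lon = runif(3, -170, 170))
  for (k in 1:10) {
    tri$lat <- runif(3, -60, 60); tri$lon <- runif(3, -170, 170)
    d <- geographic_distance(tri)
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-9)
  }
})

test_that("F_ST linearization transforms elementwise", {
  f <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  expect_equal(linearize_fst(f)[1, 2], 0.25)
  expect_equal(diag(linearize_fst(f)), c(0, 0))
  expect_error(linearize_fst(matrix(c(0, 1, 1, 0), 2, 2)), "linearized")
})

test_that("collinearity pruning enforces the cutoff and is deterministic", {
  set.seed(602)
  x <- rnorm(20)
  covs <- data.frame(a = x, b = x, c = rnorm(20))  # duplicated covariate
  kept <- prune_collinear(covs, 0.9)
  expect_true(sum(c("a", "b") %in% kept) == 1)
  expect_true("c" %in% kept)

  # nothing above the cutoff: identity
  indep <- as.data.frame(matrix(rnorm(100), 20, 5))
  expect_setequal(prune_collinear(indep, 0.9), names(indep))

  # property: no retained pair exceeds the cutoff, on randomized tables
  for (k in 1:10) {
    base <- matrix(rnorm(19 * 12), 12, 19)
    mix <- base %*% matrix(rnorm(19 * 19, sd = 0.4) + diag(19), 19, 19)
    colnames(mix) <- sprintf("B%02d", 1:19)
    kept <- prune_collinear(as.data.frame(mix), 0.9)
    if (length(kept) >= 2) {
      r <- abs(cor(mix[, kept])); diag(r) <- 0
      expect_lte(max(r), 0.9)
    }
  }

  # constant covariates are removed with a warning
  expect_warning(kc <- prune_collinear(data.frame(a = rnorm(10),
                                                  k = rep(1, 10))),
                 "constant")
  expect_identical(kc, "a")
})

test_that("pruning postcondition agrees with an established implementation", {
  skip_if_not_installed("caret")
  set.seed(603)
  base <- matrix(rnorm(10 * 12), 12, 10)
  mix <- cbind(base, base[, 1:3] + matrix(rnorm(36, sd = 0.05), 12, 3))
  colnames(mix) <- sprintf("B%02d", 1:13)
  kept <- prune_collinear(as.data.frame(mix), 0.9)
  drop_caret <- caret::findCorrelation(cor(mix), cutoff = 0.9, names = TRUE)
  kept_caret <- setdiff(colnames(mix), drop_caret)
  # both leave a violation-free set of comparable size
  r <- abs(cor(mix[, kept_caret])); diag(r) <- 0
  expect_lte(max(r), 0.9)
  expect_lte(abs(length(kept) - length(kept_caret)), 2)
})

test_that("environmental distances are z-scored Euclidean", {
  covs <- data.frame(BIO12 = c(0, 3))
  rownames(covs) <- c("p1", "p2")
  d <- environmental_distance(covs)
  expect_equal(d["p1", "p2"], sqrt(2), tolerance = 1e-9)

  samecovs <- data.frame(BIO12 = c(1, 1), BIO18 = c(2, 2))
  expect_equal(max(environmental_distance(samecovs)), 0)

  # scale invariance through z-scoring
  covs3 <- data.frame(a = rnorm(8), b = rnorm(8))
  expect_equal(environmental_distance(covs3),
               environmental_distance(transform(covs3, a = 10 * a)))
})

test_that("Mantel statistics hit their exact and degenerate cases", {
  A <- random_dist(12, seed = 604)
  m_same <- mantel_test(A, A, n_perm = 999, seed = 605)
  expect_equal(m_same$r, 1)
  expect_equal(m_same$p, 1 / 1000)

  m_neg <- mantel_test(A, -A + max(A), n_perm = 99, seed = 606)
  expect_equal(m_neg$r, -1)

  expect_error(mantel_test(A, matrix(1, 12, 12) - diag(12) * 0), "constant")
})

test_that("Mantel r agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  A <- random_dist(10, seed = 607)
  B <- 0.6 * A + 0.4 * random_dist(10, seed = 608)
  ours <- mantel_test(A, B, n_perm = 99, seed = 609)
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("partial Mantel controls the conditioning matrix", {
  set.seed(610)
  C <- random_dist(14)
  A <- 0.8 * C + 0.2 * random_dist(14)
  B <- 0.5 * C + 0.5 * random_dist(14)
  # fully controlling A by itself: residual correlation near zero
  pm_self <- partial_mantel_test(A, B, A, n_perm = 99, seed = 611)
  expect_lt(abs(pm_self$r), 0.15)
  # B = C is degenerate: residuals constant
  expect_error(partial_mantel_test(A, C, C, n_perm = 99), "constant")
  # independent C behaves like the simple Mantel
  D <- random_dist(14, seed = 612)
  ps <- partial_mantel_test(A, B, D, n_perm = 99, seed = 613)
  ms <- mantel_test(A, B, n_perm = 99, seed = 614)
  expect_equal(ps$r, ms$r, tolerance = 0.1)
})

test_that("MMRR recovers exact linear constructions and flags collinearity", {
  X1 <- random_dist(12, seed = 615)
  X2 <- random_dist(12, seed = 616)
  Y <- 2 * X1
  fit <- mmrr(Y, list(GEO = X1, ENV = X2), n_perm = 99, seed = 617)
  expect_equal(unname(fit$betas["GEO"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit$betas["ENV"]), 0, tolerance = 1e-9)
  expect_gt(fit$r_squared, 0.99)
  expect_lte(fit$beta_pvalues["GEO"], 0.05)

  expect_error(mmrr(Y, list(a = X1, b = X1), n_perm = 9), "collinear")
})

test_that("MMRR coefficients match an independent lower-triangle regression", {
  set.seed(618)
  X1 <- random_dist(14); X2 <- random_dist(14)
  Y <- 0.7 * X1 + 0.3 * X2 + random_dist(14) * 0.2
  fit <- mmrr(Y, list(a = X1, b = X2), n_perm = 49, seed = 619)
  lt <- lower.tri(Y)
  ref <- lm(Y[lt] ~ X1[lt] + X2[lt])
  expect_equal(unname(fit$betas), unname(coef(ref)), tolerance = 1e-9)
  expect_equal(fit$r_squared, summary(ref)$r.squared, tolerance = 1e-9)
})

test_that("commonality decomposition is exact and handles degenerate inputs", {
  set.seed(620)
  for (k in 1:5) {
    Y <- random_dist(12); X1 <- random_dist(12); X2 <- random_dist(12)
    ca <- commonality_two(Y, X1, X2)
    # identity against independently refit sub-models
    lt <- lower.tri(Y)
    r2 <- function(f) summary(f)$r.squared
    full <- r2(lm(Y[lt] ~ X1[lt] + X2[lt]))
    u1 <- full - r2(lm(Y[lt] ~ X2[lt]))
    u2 <- full - r2(lm(Y[lt] ~ X1[lt]))
    expect_equal(ca$r_squared, full, tolerance = 1e-9)
    expect_equal(unname(ca$unique), c(u1, u2), tolerance = 1e-9)
    expect_equal(sum(ca$unique) + ca$common, ca$r_squared, tolerance = 1e-9)
    expect_equal(unname(ca$total), unname(ca$unique + ca$common))
  }

  # orthogonal limit: X2 pure noise
  X1 <- random_dist(20, seed = 621)
  Y <- 0.9 * X1
  X2 <- random_dist(20, seed = 622)
  ca <- commonality_two(Y, X1, X2)
  expect_lt(abs(ca$common), 0.05)
  expect_gt(ca$unique[1], 0.9 * ca$r_squared)

  # identical predictors: everything is common
  ca_id <- commonality_two(Y, X1, X1)
  expect_true(ca_id$degenerate)
  expect_equal(unname(ca_id$unique), c(0, 0))
  expect_equal(ca_id$common, ca_id$r_squared)
})

test_that("covariate ranking orders predictors by association strength", {
  pops <- simulate_landscape(14, n_covariates = 4, seed = 623)
  covs <- covariate_table(pops)
  # genetic distance built to follow BIO12 exactly
  gen <- environmental_distance(covs, "BIO12")
  top <- rank_covariates(gen, covs, n_top = 2)
  expect_equal(top$covariate[1], "BIO12")
  expect_equal(top$mantel_r[1], 1, tolerance = 1e-9)
})
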