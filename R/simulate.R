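#' Simulate a sampling landscape of localities with climatic covariates
#'
#' Places localities uniformly at random in a square study area and attaches
#' spatially autocorrelated climatic covariates (a linear north--south
#' gradient plus independent Gaussian noise), emulating the kind of
#' multi-locality sampling design used in Mediterranean landscape-genomic
#' studies.
#'
#' Coordinates are synthesized on a local tangent plane centred on a fixed
#' origin and converted to latitude/longitude; all downstream distances use
#' the haversine formula so a single geodesic convention holds everywhere.
#'
#' @param n_localities number of localities (>= 2).
#' @param extent_km side length of the square study area, in km.
#' @param n_covariates number of climatic covariates to generate.
#' @param covariate_sd standard deviation of the Gaussian noise added to the
#'   latitudinal gradient of each covariate (covariate units; the gradient
#'   itself spans 2 SD units of latitude across the extent).
#' @param origin numeric length-2 vector, (lat, lon) of the study-area centre
#'   in decimal degrees.
#' @param seed integer seed.
#'
#' @return A data.frame with columns `locality`, `region` (three latitudinal
#'   bands: "South", "Center", "North"), `lat`, `lon`, and one column per
#'   covariate (`BIO12`, `BIO18`, `BIO19`, then `ENV4`, ... analogs).
#' @export
simulate_landscape <- function(n_localities, extent_km = 500,
                               n_covariates = 3, covariate_sd = 0.5,
                               origin = c(39.0, 22.5), seed = NULL) {
  if (n_localities < 2) stop("n_localities must be >= 2")
  if (extent_km <= 0) stop("extent_km must be positive")
  if (n_covariates < 1) stop("n_covariates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  km_per_deg_lat <- 111.19493  # pi/180 * 6371.0088
  for (attempt in 1:100) {
    xy <- matrix(stats::runif(2 * n_localities, -extent_km / 2, extent_km / 2),
                 ncol = 2)
    lat <- origin[1] + xy[, 2] / km_per_deg_lat
    lon <- origin[2] + xy[, 1] / (km_per_deg_lat * cos(origin[1] * pi / 180))
    if (!anyDuplicated(cbind(lat, lon))) break
  }
  if (anyDuplicated(cbind(lat, lon))) stop("could not place unique coordinates")

  # covariates: linear N-S gradient (2 units across the extent) + noise
  z_lat <- (lat - origin[1]) / (extent_km / 2 / km_per_deg_lat)
  cov_names <- c("BIO12", "BIO18", "BIO19",
                 if (n_covariates > 3) paste0("ENV", 4:n_covariates))
  cov_names <- cov_names[seq_len(n_covariates)]
  covs <- vapply(seq_len(n_covariates), function(k) {
    z_lat + stats::rnorm(n_localities, sd = covariate_sd)
  }, numeric(n_localities))
  covs <- matrix(covs, nrow = n_localities,
                 dimnames = list(NULL, cov_names))

  region <- cut(lat, breaks = stats::quantile(lat, c(0, 1/3, 2/3, 1)),
                labels = c("South", "Center", "North"), include.lowest = TRUE)
  out <- data.frame(
    locality = sprintf("L%02d", seq_len(n_localities)),
    region = as.character(region),
    lat = lat, lon = lon,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(covs))
}

#' Extract the covariate columns of a locality table
#'
#' @param pops a locality table from [simulate_landscape()] or read with
#'   [read_population_table()].
#' @return data.frame of covariate columns, rownames = locality ids.
#' @export
covariate_table <- function(pops) {
  covs <- pops[, setdiff(names(pops), c("locality", "region", "lat", "lon")),
               drop = FALSE]
  rownames(covs) <- pops$locality
  covs
}

#' Simulate spatially structured population allele frequencies
#'
#' Per locus an ancestral frequency p0 ~ Uniform(0.05, 0.95) is drawn;
#' population frequencies are the inverse-logit of logit(p0) plus a
#' multivariate Gaussian deviate with exponentially distance-decaying
#' covariance `base_sd^2 * exp(-d_jk / ibd_range)` (d_jk = haversine distance
#' in km), producing isolation by distance. A chosen subset of "adaptive"
#' loci additionally receives `effect_size` times the z-scored value of one
#' climatic covariate on the logit scale, producing isolation by environment.
#' Frequencies are clamped to [0.001, 0.999].
#'
#' @param pops locality table (see [simulate_landscape()]).
#' @param n_loci number of loci.
#' @param base_sd logit-scale SD of the spatial deviation (drift intensity).
#' @param ibd_range distance-decay scale of the frequency correlation, km.
#' @param n_adaptive number of adaptive loci (<= n_loci).
#' @param effect_size logit-scale shift per covariate SD at adaptive loci.
#' @param covariate_name name of the covariate driving adaptive loci.
#' @param seed integer seed.
#'
#' @return A list of class `"sim_truth"` with elements `freq` (n_loci x J
#'   matrix, columns named by locality), `adaptive` (logical length n_loci),
#'   `pops`, and the generator parameters.
#' @export
simulate_allele_frequencies <- function(pops, n_loci, base_sd = 0.5,
                                        ibd_range = 200, n_adaptive = 0,
                                        effect_size = 0,
                                        covariate_name = "BIO12",
                                        seed = NULL) {
  if (base_sd <= 0) stop("base_sd must be positive")
  if (ibd_range <= 0) stop("ibd_range must be positive")
  if (n_adaptive > n_loci) stop("n_adaptive must be <= n_loci")
  if (!is.null(seed)) set.seed(seed)

  J <- nrow(pops)
  d <- geographic_distance(pops, log_transform = FALSE)
  Sigma <- base_sd^2 * exp(-d / ibd_range)
  # numerical jitter keeps the Cholesky stable at very short ranges
  ch <- chol(Sigma + diag(1e-10, J))

  p0 <- stats::runif(n_loci, 0.05, 0.95)
  eta <- matrix(stats::rnorm(n_loci * J), n_loci, J) %*% ch
  eta <- eta + stats::qlogis(p0)

  adaptive <- rep(FALSE, n_loci)
  if (n_adaptive > 0) {
    adaptive[sample.int(n_loci, n_adaptive)] <- TRUE
    z_env <- as.numeric(scale(pops[[covariate_name]]))
    eta[adaptive, ] <- eta[adaptive, , drop = FALSE] +
      effect_size * matrix(z_env, sum(adaptive), J, byrow = TRUE)
  }
  freq <- stats::plogis(eta)
  freq <- pmin(pmax(freq, 0.001), 0.999)
  dimnames(freq) <- list(sprintf("site_%05d", seq_len(n_loci)), pops$locality)

  structure(list(freq = freq, adaptive = adaptive, pops = pops,
                 base_sd = base_sd, ibd_range = ibd_range,
                 effect_size = effect_size, covariate_name = covariate_name),
            class = "sim_truth")
}

#' Draw tetraploid genotypes (dosages) from population allele frequencies
#'
#' Under tetrasomic inheritance (autotetraploid, all four homologues pair
#' freely) the dosage at a locus with frequency p is Binomial(4, p). Under
#' disomic inheritance (allotetraploid, two fixed subgenomes) the dosage is
#' the sum of two Binomial(2, .) draws at subgenome frequencies
#' p +/- delta/2 (clamped to [0, 1]), where `subgenome_divergence` delta
#' tunes the fixed difference between subgenomes; delta = 0 reduces exactly
#' to the tetrasomic model and delta = 1 at p = 0.5 gives fixed duplex
#' heterozygosity (all dosage 2).
#'
#' @param truth a `"sim_truth"` object with `$freq` populated.
#' @param n_per_pop individuals sampled per locality.
#' @param mode `"tetrasomic"` or `"disomic"`.
#' @param subgenome_divergence delta in [0, 1]; disomic mode only.
#' @param seed integer seed.
#'
#' @return The input truth with added `dosage` (individuals x loci integer
#'   matrix, rownames `<locality>_<k>`), `membership` (locality of each
#'   individual) and `mode`.
#' @export
draw_genotypes <- function(truth, n_per_pop, mode = c("tetrasomic", "disomic"),
                           subgenome_divergence = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(truth$freq)) stop("truth$freq must be populated")
  if (subgenome_divergence < 0 || subgenome_divergence > 1)
    stop("subgenome_divergence must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  freq <- truth$freq
  L <- nrow(freq); J <- ncol(freq)
  n <- n_per_pop * J
  membership <- rep(colnames(freq), each = n_per_pop)
  ids <- paste0(membership, "_", rep(seq_len(n_per_pop), times = J))

  # per-individual frequency matrix (n x L)
  P <- t(freq)[membership, , drop = FALSE]
  if (mode == "tetrasomic") {
    dosage <- matrix(stats::rbinom(n * L, 4, as.numeric(P)), n, L)
  } else {
    d2 <- subgenome_divergence / 2
    p1 <- pmin(pmax(P + d2, 0), 1)
    p2 <- pmin(pmax(P - d2, 0), 1)
    dosage <- matrix(stats::rbinom(n * L, 2, as.numeric(p1)) +
                     stats::rbinom(n * L, 2, as.numeric(p2)), n, L)
  }
  dimnames(dosage) <- list(ids, rownames(freq))
  truth$dosage <- dosage
  truth$membership <- stats::setNames(membership, ids)
  truth$mode <- mode
  truth$subgenome_divergence <- subgenome_divergence
  truth
}

#' Simulate RAD-seq read counts from true dosages
#'
#' Sequencing depth per individual-site cell is Negative-Binomial with the
#' given mean and dispersion (size), honouring the overdispersed coverage of
#' real RAD-seq (e.g. mean 16x, SD about 6x). Each read is independently
#' recorded as a third ("other") allele with probability `error_rate / 2`;
#' otherwise it reports the alternative allele with probability g/4,
#' miscalled to the opposite allele with probability `error_rate / 2`.
#'
#' @param dosage individuals x sites integer matrix in 0..4.
#' @param mean_depth mean sequencing depth per cell.
#' @param depth_dispersion Negative-Binomial size parameter; the depth SD is
#'   `sqrt(mu + mu^2/size)` (size 8 at mean 16 gives SD ~ 6.9).
#' @param error_rate total sequencing error rate in [0, 0.1], split equally
#'   between cross-allele flips and third-allele reads.
#' @param seed integer seed.
#'
#' @return A list of class `"read_counts"` with integer matrices `ref`,
#'   `alt`, `other` (individuals x sites) sharing dimnames with `dosage`.
#' @export
simulate_read_counts <- function(dosage, mean_depth = 16,
                                 depth_dispersion = 8, error_rate = 0.005,
                                 seed = NULL) {
  if (any(dosage < 0 | dosage > 4)) stop("dosages must be in 0..4")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  if (mean_depth <= 0 || depth_dispersion <= 0)
    stop("mean_depth and depth_dispersion must be positive")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(dosage); L <- ncol(dosage); N <- n * L
  depth <- stats::rnbinom(N, size = depth_dispersion, mu = mean_depth)
  e2 <- error_rate / 2
  other <- stats::rbinom(N, depth, e2)
  rest <- depth - other
  # P(read reports alt | not other) = (g/4)(1 - e/2) + (1 - g/4) e/2
  g4 <- as.numeric(dosage) / 4
  p_alt <- g4 * (1 - e2) + (1 - g4) * e2
  alt <- stats::rbinom(N, rest, p_alt)
  ref <- rest - alt

  dn <- dimnames(dosage)
  out <- list(ref = matrix(ref, n, L, dimnames = dn),
              alt = matrix(alt, n, L, dimnames = dn),
              other = matrix(other, n, L, dimnames = dn))
  out <- lapply(out, function(m) { storage.mode(m) <- "integer"; m })
  structure(out, class = "read_counts")
}

#' Simulate a complete tetraploid RAD-seq dataset
#'
#' Convenience wrapper chaining [simulate_landscape()],
#' [simulate_allele_frequencies()], [draw_genotypes()] and
#' [simulate_read_counts()] under one seed. Defaults emulate the study
#' regime the package targets: 16 localities, 9 tetraploid individuals each,
#' 94-bp RAD loci with one SNP per locus, mean depth 16x with overdispersion.
#'
#' @param n_localities,n_per_pop,n_loci design sizes.
#' @param extent_km,n_covariates,covariate_sd landscape parameters.
#' @param base_sd,ibd_range,n_adaptive,effect_size,covariate_name
#'   allele-frequency model parameters.
#' @param mode,subgenome_divergence inheritance model.
#' @param mean_depth,depth_dispersion,error_rate read model.
#' @param seed integer seed governing all stages.
#'
#' @return A `"sim_truth"` object with `freq`, `adaptive`, `dosage`,
#'   `membership`, `pops` and `reads` (a `"read_counts"` object).
#' @export
simulate_dataset <- function(n_localities = 16, n_per_pop = 9, n_loci = 5000,
                             extent_km = 500, n_covariates = 3,
                             covariate_sd = 0.5,
                             base_sd = 0.5, ibd_range = 200,
                             n_adaptive = 0, effect_size = 0,
                             covariate_name = "BIO12",
                             mode = "tetrasomic", subgenome_divergence = 0,
                             mean_depth = 16, depth_dispersion = 8,
                             error_rate = 0.005, seed = 1) {
  pops <- simulate_landscape(n_localities, extent_km, n_covariates,
                             covariate_sd, seed = seed)
  truth <- simulate_allele_frequencies(pops, n_loci, base_sd, ibd_range,
                                       n_adaptive, effect_size,
                                       covariate_name, seed = seed + 1L)
  truth <- draw_genotypes(truth, n_per_pop, mode, subgenome_divergence,
                          seed = seed + 2L)
  truth$reads <- simulate_read_counts(truth$dosage, mean_depth,
                                      depth_dispersion, error_rate,
                                      seed = seed + 3L)
  truth
}
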