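#' Genotype-class frequencies as a function of allele frequency
#'
#' For every site with no missing calls, computes the sample allele
#' frequency q = sum(g) / 4n and the empirical proportions of the five
#' dosage classes, then averages the class proportions within
#' allele-frequency bins. Under tetrasomic inheritance the binned curves
#' follow Binomial(4, q): all five classes appear at intermediate q and the
#' three heterozygote curves peak near q = 0.25, 0.5, 0.75 with similar
#' heights at q = 0.5. Under disomic inheritance with diverged subgenomes
#' the duplex class (g = 2) dominates at intermediate q.
#'
#' @param dosage individuals x sites matrix in 0..4 (NA = missing), or a
#'   `"tetra_genotypes"` object.
#' @param bin_width allele-frequency bin width.
#' @return An object of class `"inheritance_profile"`: data.frame-backed
#'   list with `bin_centers`, `class_freq` (bins x 5), `n_sites_per_bin`,
#'   and the per-site `q` and class proportions. Supports `plot()`.
#' @export
genotype_frequency_profile <- function(dosage, bin_width = 0.02) {
  if (inherits(dosage, "tetra_genotypes")) dosage <- dosage$dosage
  complete <- colSums(is.na(dosage)) == 0
  if (!any(complete)) stop("no sites without missing calls")
  g <- dosage[, complete, drop = FALSE]
  n <- nrow(g)
  q <- colSums(g) / (4 * n)
  props <- vapply(0:4, function(k) colMeans(g == k), numeric(ncol(g)))
  props <- matrix(props, ncol = 5,
                  dimnames = list(colnames(g), paste0("g", 0:4)))

  breaks <- seq(0, 1, by = bin_width)
  bin <- cut(q, breaks, include.lowest = TRUE)
  class_freq <- apply(props, 2, function(p)
    tapply(p, bin, mean))
  class_freq <- matrix(class_freq, ncol = 5,
                       dimnames = list(levels(bin), paste0("g", 0:4)))
  n_per_bin <- as.integer(table(bin))

  structure(list(bin_centers = breaks[-1] - bin_width / 2,
                 class_freq = class_freq,
                 n_sites_per_bin = n_per_bin,
                 q = q, site_props = props, bin_width = bin_width),
            class = "inheritance_profile")
}

#' @export
print.inheritance_profile <- function(x, ...) {
  cat(sprintf("Genotype-frequency profile: %d complete-case sites, %d bins of width %.3g\n",
              length(x$q), length(x$bin_centers), x$bin_width))
  invisible(x)
}

#' @export
plot.inheritance_profile <- function(x, ...) {
  filled <- x$n_sites_per_bin > 0
  graphics::matplot(x$bin_centers[filled], x$class_freq[filled, ],
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "#1b9e77", "#d95f02", "#7570b3", "grey40"),
                    xlab = "allele frequency", ylab = "genotype-class frequency",
                    ...)
  graphics::legend("top", legend = paste0("g=", 0:4), lty = 1, lwd = 2,
                   col = c("black", "#1b9e77", "#d95f02", "#7570b3", "grey40"),
                   horiz = TRUE, bty = "n")
  invisible(x)
}

#' Triplex-to-duplex heterozygote balance
#'
#' Over sites with allele frequency in `band`, the ratio
#' D = (mean simplex freq + mean triplex freq) / mean duplex freq.
#' Under exact tetrasomic Binomial(4, 0.5) proportions D = (4/16 + 4/16) /
#' (6/16) = 4/3; fixed-difference disomic data give D = 0 (all duplex).
#' Drift and structure push D above 4/3 in real autotetraploid data.
#'
#' @param dosage dosage matrix or `"tetra_genotypes"` object.
#' @param band numeric length-2 allele-frequency band.
#' @param min_sites minimum number of sites required inside the band.
#' @return D, a non-negative scalar.
#' @export
heterozygote_balance <- function(dosage, band = c(0.4, 0.6), min_sites = 50) {
  prof <- genotype_frequency_profile(dosage, bin_width = 0.02)
  sel <- prof$q >= band[1] & prof$q <= band[2]
  if (!any(sel)) stop("no sites with allele frequency inside the band")
  if (sum(sel) < min_sites)
    warning(sprintf("only %d sites in band (floor %d)", sum(sel), min_sites))
  p <- colMeans(prof$site_props[sel, , drop = FALSE])
  if (p["g2"] == 0) stop("no duplex genotypes in band; D undefined")
  as.numeric((p["g1"] + p["g3"]) / p["g2"])
}

# expected class distribution at frequency q under each inheritance model
tetrasomic_expectation <- function(q) stats::dbinom(0:4, 4, q)

disomic_expectation <- function(q) {
  # extreme fixed-difference allotetraploid: one subgenome carries all the
  # variation; for q <= 0.5 dosage = Binomial(2, 2q), for q >= 0.5
  # dosage = 2 + Binomial(2, 2q - 1); point mass on g = 2 at q = 0.5
  if (q <= 0.5) c(stats::dbinom(0:2, 2, 2 * q), 0, 0)
  else c(0, 0, stats::dbinom(0:2, 2, 2 * q - 1))
}

#' Classify inheritance mode from a genotype-frequency profile
#'
#' Compares the observed genotype-class distribution in the intermediate
#' allele-frequency band to the tetrasomic expectation Binomial(4, q) and
#' to the extreme fixed-difference disomic expectation, by total-variation
#' distance averaged over populated bins (weighted by sites per bin). The
#' label is the nearer model; when the two distances differ by less than
#' `margin` the call is "ambiguous" — intermediate allotetraploids land
#' there by design.
#'
#' @param profile an `"inheritance_profile"`.
#' @param band allele-frequency band to score.
#' @param margin ambiguity margin on the TV-distance difference.
#' @return A list with `label` ("tetrasomic", "disomic" or "ambiguous"),
#'   `score` (disomic minus tetrasomic distance; positive favours
#'   tetrasomic), `tv_tetrasomic`, `tv_disomic`.
#' @export
classify_inheritance <- function(profile, band = c(0.4, 0.6), margin = 0.05) {
  sel <- profile$bin_centers >= band[1] & profile$bin_centers <= band[2] &
    profile$n_sites_per_bin > 0
  if (!any(sel)) stop("no populated bins inside the band")
  obs <- profile$class_freq[sel, , drop = FALSE]
  qs <- profile$bin_centers[sel]
  wts <- profile$n_sites_per_bin[sel]
  tv <- function(a, b) sum(abs(a - b)) / 2
  d_tet <- sum(wts * vapply(seq_along(qs), function(i)
    tv(obs[i, ], tetrasomic_expectation(qs[i])), numeric(1))) / sum(wts)
  d_dis <- sum(wts * vapply(seq_along(qs), function(i)
    tv(obs[i, ], disomic_expectation(qs[i])), numeric(1))) / sum(wts)
  label <- if (abs(d_tet - d_dis) < margin) "ambiguous"
           else if (d_tet < d_dis) "tetrasomic" else "disomic"
  structure(list(label = label, score = d_dis - d_tet,
                 tv_tetrasomic = d_tet, tv_disomic = d_dis),
            class = "inheritance_call")
}

#' @export
print.inheritance_call <- function(x, ...) {
  cat(sprintf("Inheritance mode: %s\n", x$label))
  cat(sprintf("  TV distance to tetrasomic expectation: %.3f\n",
              x$tv_tetrasomic))
  cat(sprintf("  TV distance to disomic expectation   : %.3f\n",
              x$tv_disomic))
  invisible(x)
}

#' Write an inheritance profile as TSV
#'
#' @param profile an `"inheritance_profile"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(bin_center = profile$bin_centers,
                   profile$class_freq,
                   n_sites = profile$n_sites_per_bin,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
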