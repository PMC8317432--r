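---
title: "Methods: ploidy-aware population genomics for autotetraploid RAD-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy-aware population genomics for autotetraploid RAD-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tetrapop implements a complete population-genomic workflow for
autotetraploid organisms genotyped by RAD-seq, where every individual
carries 0–4 copies of the alternative allele at a biallelic SNP and the
copy number (dosage) must be inferred from read counts. The package is
organized as a chain of independently usable stages, each validated
against a seeded synthetic-data generator that knows the truth it hides.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions every
downstream guarantee is stated under.

**Landscape.** `simulate_landscape()` places localities uniformly in a
square (default 500 km side, matching a country-scale sampling design of
16 localities), converts tangent-plane coordinates to latitude/longitude,
and attaches climatic covariates built as a linear north–south gradient
plus Gaussian noise (SD 0.5 in gradient units), so covariates are
spatially autocorrelated the way real bioclimatic variables (e.g. the
precipitation variables BIO12/BIO18/BIO19) are. All distances everywhere
in the package are haversine great-circle distances with Earth radius
6371.0088 km — one geodesic convention throughout.

**Allele frequencies.** Per locus an ancestral frequency is drawn from
Uniform(0.05, 0.95) (a configurable stand-in: no minor-allele-frequency
spectrum is available for the motivating system) and population
frequencies are the inverse-logit of a multivariate Gaussian field with
covariance $\sigma^2 e^{-d_{jk}/\rho}$ over geographic distance
($\sigma$ = `base_sd` = 0.5, $\rho$ = `ibd_range` = 200 km). This is the
simplest model producing isolation by distance with a tunable range, and
it is analytically checkable (the logit-scale correlation decays
exponentially by construction). A chosen fraction of "adaptive" loci
additionally receives `effect_size` × the z-scored value of one covariate
on the logit scale, producing isolation by environment. Loci are
independent, as unlinked RAD tags effectively are; no coalescent or
forward simulation is attempted, so the generator reproduces moment
structure (drift variance, spatial correlation, environmental clines) but
not site-frequency-spectrum details or linkage.

**Genotypes.** Tetrasomic inheritance draws dosage ~ Binomial(4, p);
disomic inheritance draws the sum of two Binomial(2, ·) subgenome
contributions at p ± δ/2, where δ (`subgenome_divergence`) interpolates
exactly between the tetrasomic model (δ = 0) and fixed duplex
heterozygosity (δ = 1 at p = 0.5).

**Reads.** Depth is Negative-Binomial (mean 16, size 8, giving SD ≈ 6.9)
rather than Poisson, honouring the overdispersion of real RAD coverage at
a mean of 16×. Each read is recorded as a third allele with probability
`error_rate`/2 and flipped between the two focal alleles with probability
`error_rate`/2; the symmetric split gives the per-site error estimator a
signal to recover. Default `error_rate` is 0.005.

## Empirical-Bayes dosage calling

For each site, the error rate is estimated from third-allele reads with
pseudocounts, $\hat\varepsilon = (1 + \sum \text{other})/(2 + \sum
\text{total})$, clamped to $[10^{-4}, 0.1]$ so likelihoods stay proper.
Genotype likelihoods use the binomial read model with
$h_g = (g/4)(1-\varepsilon) + (1-g/4)\varepsilon$. An EM iterates between
dosage posteriors under a Binomial(4, q) tetrasomic-mating prior and the
frequency update $q \leftarrow \sum_i \mathbb{E}[g_i]/4n$ (tolerance
$10^{-6}$ on $\Delta q$, 100 iterations, observed-data log-likelihood
non-decreasing by construction and asserted in tests). Dosage is the
posterior argmax; near-ties are broken deterministically toward the
dosage nearest $4\hat q$, which keeps the caller exactly equivariant
under swapping the reference and alternative labels ($g \mapsto 4-g$).

Cells below 5 reads are missing; sites are dropped when more than 10% of
individuals are missing, the minor allele frequency falls below 0.05
(configurable; conventional at this sample size), or fewer than two
called individuals carry each allele — the latter is this package's
singleton-noise guard standing in for an upstream site-quality filter
that has no analog in a self-contained caller. A tetrasomic
Hardy–Weinberg prior is used throughout; inbreeding coefficients near
zero in the data regimes targeted justify this.

**What accuracy to expect.** At 16× mean depth the binomial success
probabilities of adjacent dosages differ by only 0.25, and no decision
rule can fully separate them: exact enumeration of the read model (depth
≥ 5, frequencies Uniform(0.05, 0.95), the true population frequency
known) bounds mean per-cell concordance at 86.7%. The caller reaches
85.8–86.0% under those conditions — within a point of the bound — and
concordance rises monotonically with depth (asserted at means 5, 10, 20,
50). Statistics that average over individuals (allele frequencies, He,
F_ST, XtX) are far more accurate than individual cells: the EM frequency
estimates have mean absolute error ≈ 0.006 at n = 150. Tests assert the
measured concordance regime, not a hoped-for one; on real data with a
skewed frequency spectrum (most SNPs rare) per-cell concordance will be
substantially higher than under the uniform spectrum used here.

## Inheritance diagnosis

`genotype_frequency_profile()` recreates the classic dosage-vs-frequency
diagnostic from complete-case sites: under tetrasomic inheritance all
five classes appear at intermediate frequency and the three heterozygote
curves have comparable heights; under disomic inheritance with diverged
subgenomes the duplex class dominates. Bin width 0.02 and the scoring
band [0.4, 0.6] are exposed parameters. `heterozygote_balance()` reports
D = (simplex + triplex)/duplex, 4/3 under exact Binomial(4, 0.5)
proportions and 0 for fixed-difference allotetraploids; drift and
structure push D above 4/3, so D is reported without interpretation.
`classify_inheritance()` compares the observed band-averaged class
distribution by total-variation distance to the tetrasomic expectation
and to the extreme fixed-difference disomic expectation, labelling by the
nearer model with an ambiguity margin of 0.05. Because the disomic
reference is the extreme case, mildly diverged allotetraploids (δ ≈ 0.4)
sit closer to the tetrasomic expectation and are labelled accordingly;
the diagnostic is decisive only toward the ends of the continuum, which
mirrors how such evidence is used in practice (label recovery is ≥ 95%
over 100 seeded replicates per mode at δ ∈ {0.8, 1}).

## Diversity and differentiation

Per-locality statistics use allele-copy counts m = 4·(called
individuals): unbiased gene diversity Hs = m/(m−1)·2q(1−q); He is the
mean over retained SNPs (monomorphic-within-locality SNPs count as zero);
Ho averages the within-individual heterozygosity g(4−g)/6 (the fraction
of heterozygous pairs among the six copy-pairs of a tetraploid); F_IS =
1 − Ho/He; π divides the summed site Hs by total callable bases (default
SNPs × 94 bp, the RAD locus length, exposed as a parameter), so π·bp /
n_SNPs equals mean Hs exactly — an identity asserted in tests. Private
alleles are counted at the allele level and corrected by (n+1)/n.
Pairwise F_ST uses H_T = 2q̄(1−q̄) from the unweighted mean of the two
locality frequencies and unbiased H_S, combined as a ratio of sums over
sites (stable at low-diversity sites), clamped at zero. The H_T term
carries a small-sample downward bias of order 1/(2m); at the shallow
differentiation the default generator produces (true F_ST ~ 0.01) this
visibly truncates near-zero pairs, while at real-data differentiation
levels (F_ST 0.1–0.4) it is negligible. Regional summaries report mean ±
SE (sample SD/√k).

## Individual structure

Relatedness is a correlation-form method-of-moments estimator on
complete-case SNPs: dosages centred by 4q̂, pairs normalized by their own
norms, giving unit self-relatedness and values in [−1, 1]. This is a
deliberate, documented choice among moment estimators (bounded, exactly
swap-invariant), not a numerical clone of any external program. PCA
eigendecomposes the individual covariance of (optionally mean-imputed)
centred dosages; per-axis signs are fixed so the largest-magnitude score
is positive, making output bit-reproducible under fixed input order.

## Isolation by distance vs isolation by environment

Genetic distances are linearized F_ST/(1−F_ST); geographic distances are
log-transformed haversine km (natural log — the base only rescales
regression coefficients); environmental distances are Euclidean on
z-scored covariates. Covariates are pruned greedily at |r| > 0.9
(removing from the worst pair the variable with the larger mean absolute
correlation, ties by name), then ranked by per-covariate simple Mantel r
against the genetic matrix — a transparent, stated substitute for
machine-learning covariate ranking; the top three are used.

Mantel and partial Mantel tests correlate lower triangles with one-sided
(greater) permutation p-values (999 permutations), permuting rows and
columns of one matrix jointly; the partial variant correlates OLS
residuals after regressing both matrices on the control. MMRR regresses
the genetic lower triangle on the predictors, with per-coefficient and
model significance from re-fitted t- and F-statistics under joint
row/column permutation of the response (1000 permutations); coefficients
are reported on the raw scale with standardized versions alongside, since
either convention appears in the literature. Commonality analysis
decomposes the two-predictor R² into unique components (full R² minus
each single-predictor R²) and the common remainder; the identity
U₁ + U₂ + C = R² is asserted to 10⁻⁹, and identical predictors are
handled as a flagged degenerate case (all variance common). Permutation
type-I error is calibrated empirically: both Mantel and MMRR reject at
4–5% at α = 0.05 over 1000 null replicates.

## Selection scan

Population frequencies (from called dosages aggregated to allele counts)
are standardized by the size-weighted locus mean,
$z_{lj} = (p_{lj} - \bar p_l)/\sqrt{\bar p_l(1-\bar p_l)}$, and the
population covariance Ω = Z'Z/L is shrunk linearly toward its diagonal
(weight 0.05). The shrinkage is load-bearing: weighted centering makes Z
exactly rank J−1, so the raw Ω is singular, and the neutral mean of the
quadratic form XtX = z'Ω⁻¹z is J−1 (not J) by the trace identity.
Environmental association is the Pearson correlation of the locus vector
and the z-scored covariate after both are whitened by Ω^(−1/2): a
deterministic, structure-corrected surrogate for a Bayes factor, monotone
in association strength. This surrogate — not a re-implementation of any
MCMC machinery — is the package's headline approximation and is stated in
its outputs.

Thresholds come from pseudo-observed data (PODs): 100,000 neutral loci
with locus means resampled from the data, Gaussian deviates from Ω,
frequencies back-transformed, clamped, and re-standardized through the
identical code path as real loci. Outliers are flagged conservatively
(XtX above its 99% POD quantile plus an association above its 99.9%
quantile) and very conservatively (XtX above 99.9%). One honest
calibration caveat, quantified in the tests: the Gaussian POD is
homoscedastic while generator loci have frequency-dependent scales, so
real neutral data exceed the 99% POD threshold at ≈ 1.6–2.2% rather than
1% (the 99.9% threshold is much closer to nominal). The conservative
criteria intersect XtX with the association quantile precisely to absorb
this. At effect size 0.8 (50 adaptive loci in 5000) the intersection
outliers are ~95-fold enriched for true adaptive loci, with top-1%
association sensitivity ≈ 0.8, and power rises monotonically with effect
size.

## Orchestration and reproducibility

`pipeline_config()` holds every constant in one place (depth filter 5,
missingness 0.10, MAF 0.05, 999/1000 permutations, collinearity cutoff
0.9, 100,000 PODs, quantiles 0.99/0.999); a test asserts each default.
One global seed fans out to fixed per-stage seeds, so toggling a stage
does not perturb another's randomness; manifests record parameters,
seeds, and content hashes, and reruns are bit-identical. Problem sizes
used by the test-suite guarantees — chosen to make the checks sharp while
keeping a laptop run comfortable — are stated inline above (e.g. 16 × 9 ×
2000–6000 loci for recovery and calibration, 1000 replicates for
permutation calibration, 100 replicates per inheritance mode).

## Known limitations

Only biallelic SNPs in tetraploids (ploidy is a parameter of the
interfaces but only 4 is exercised); no multiallelic sites or indels; no
admixture/clustering inference (PCA and relatedness stand in); no
linkage-aware outlier clustering; the MAF spectrum of the generator is a
uniform stand-in; the relatedness and F_ST estimators are this package's
stated definitions of standard polysomic analogs, not numerical clones of
external tools.
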