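# tetrapop

Ploidy-aware population genomics for autotetraploid RAD-seq data.

Quantifying genetic variation in polyploids is hard because a tetraploid
genotype is a *dosage* — 0–4 copies of the alternative allele — that must
be inferred from noisy read counts, and because inheritance may be
tetrasomic (autopolyploid: dosage ~ Binomial(4, p) under random mating)
or disomic (allopolyploid: two fixed subgenomes inflate duplex AAaa
heterozygotes). tetrapop packages the full analysis chain a landscape
genomicist needs for such systems — written for population studies like
the Greek *Alkanna tinctoria* sampling design it emulates (≈16 localities
× 9 tetraploid individuals, 94-bp RAD loci, 16× ± 6× coverage):

1. **Simulation** — a seeded generator of landscapes, spatially
   autocorrelated allele-frequency fields (logit-MVN with exponential
   distance decay), tetrasomic/disomic dosages, and overdispersed read
   counts, with truth tables for every stage.
2. **Genotyping** — empirical-Bayes dosage calling: per-site error rates
   ε̂ = (1+Σother)/(2+Σtotal), binomial likelihoods with
   h_g = (g/4)(1−ε) + (1−g/4)ε, an EM over a Binomial(4, q) population
   prior, and the standard filters (depth ≥ 5, ≤ 10% missing, MAF ≥ 0.05).
3. **Inheritance diagnosis** — genotype-class frequencies vs allele
   frequency, the triplex/duplex balance D (4/3 under exact tetrasomic
   HWE), and a total-variation classifier (tetrasomic / disomic /
   ambiguous).
4. **Diversity & differentiation** — π, He (unbiased Hs = m/(m−1)·2q(1−q)),
   Ho via g(4−g)/6, F_IS, pairwise F_ST (ratio of sums), private alleles
   with the (n+1)/n small-sample correction, regional mean ± SE.
5. **Individual structure** — method-of-moments relatedness and PCA on the
   dosage covariance.
6. **IBD vs IBE** — haversine/log geographic and z-scored environmental
   distances, collinearity pruning (|r| > 0.9), simple and partial Mantel
   (999 permutations), MMRR (1000 permutations), commonality analysis.
7. **Selection scan** — structure-corrected XtX (z'Ω⁻¹z on standardized
   population frequencies), whitened-correlation environmental
   association, and outlier thresholds calibrated on 100,000 neutral
   pseudo-observed loci (99% / 99.9% quantiles).

## Worked example

```r
library(tetrapop)

truth <- simulate_dataset(n_localities = 16, n_per_pop = 9,
                          n_loci = 2000, seed = 1)
calls <- call_genotypes(truth$reads)
print(calls)
#> Tetraploid genotype calls
#>   individuals : 144
#>   sites       : 1972 retained of 2000 input
#>   missing     : 1.91% of retained cells
#>   filters     : min_depth=5, max_missing=0.10, maf>=0.05

classify_inheritance(genotype_frequency_profile(calls))
#> Inheritance mode: tetrasomic
#>   TV distance to tetrasomic expectation: 0.050
#>   TV distance to disomic expectation   : 0.483
```

All five dosage classes are present at intermediate allele frequencies
and the observed class distribution sits 10× closer (total-variation
distance 0.050 vs 0.483) to the Binomial(4, q) expectation than to the
fixed-difference disomic model — the signature of tetrasomic inheritance.

```r
gen <- linearize_fst(pairwise_fst(calls, truth$membership))
geo <- geographic_distance(truth$pops, log_transform = TRUE)
env <- environmental_distance(covariate_table(truth$pops))

mantel_test(gen, geo, n_perm = 999, seed = 2)
#> Mantel test: r = 0.725, p = 0.001 (999 permutations)

mmrr(gen, list(GEO = geo, ENV = env), n_perm = 1000, seed = 3)
#> Multiple matrix regression with randomization
#>   R^2 = 0.5365 (model p = 0.000999, 1000 permutations)
#>   beta[GEO] = 0.002116 (std 0.660, p = 0.000999)
#>   beta[ENV] = 0.0001834 (std 0.124, p = 0.1429)
```

This simulation contained isolation by distance and no environmental
effect, and the decomposition recovers exactly that: a strong,
significant geographic coefficient and a non-significant environmental
one. With `effect_size > 0` the ENV term becomes significant and the
selection scan's conservative outliers (XtX above the 99% POD quantile
*and* association above the 99.9% quantile) are ~95-fold enriched for the
truly adaptive loci.

The whole chain can also be driven by one configuration object:

```r
cfg <- pipeline_config(seed = 1)       # every default in one place
run_pipeline(cfg, "results/run1")      # writes TSVs + manifest with hashes
```

or from the shell:

```sh
Rscript scripts/run_pipeline.R --out results/run1 --seed 1
```

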