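Package: tetrapop
Title: Ploidy-Aware Population Genomics for Autotetraploid RAD-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for population-genomic analysis of
    autotetraploid RAD-seq data: empirical-Bayes tetraploid genotype (dosage)
    calling from allele read counts with per-site error rates and EM allele
    frequency priors; diagnosis of tetrasomic versus disomic inheritance from
    genotype-class frequency spectra; polysomic diversity and differentiation
    statistics (nucleotide diversity, gene diversity, inbreeding, pairwise
    FST, private alleles with small-sample correction); decomposition of
    isolation by distance versus isolation by environment with Mantel tests,
    multiple matrix regression with randomization (MMRR) and commonality
    analysis; and a structure-corrected XtX-style outlier and
    genotype-environment association scan calibrated with pseudo-observed
    datasets. A seeded synthetic-data generator emulating a multi-locality
    tetraploid RAD-seq study provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    caret,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
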