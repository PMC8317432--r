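#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline.
#
#   Rscript scripts/run_pipeline.R --out results/run1 [--config cfg.yaml]
#     [--seed 1] [--stages simulate,genotype,diagnose,diversity,structure,ibd_ibe,scan]

suppressPackageStartupMessages({
  library(optparse)
  library(tetrapop)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML pipeline configuration [default: package defaults]"),
  make_option("--out", type = "character", default = "pipeline_out",
              help = "output directory [default: %default]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "global seed override"),
  make_option("--stages", type = "character", default = NULL,
              help = "comma-separated stage subset"))))

cfg <- if (is.null(opts$config)) pipeline_config() else read_config(opts$config)
if (!is.null(opts$seed)) cfg$seed <- opts$seed
if (!is.null(opts$stages))
  cfg$stages <- strsplit(opts$stages, ",")[[1]]

run_pipeline(cfg, opts$out)
message("pipeline complete: ", opts$out)
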