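#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: the genotype
#' filters (min_depth 5, max_missing 0.10, maf_min 0.05), the permutation
#' counts (999 for Mantel, 1000 for MMRR), the collinearity cutoff (0.9),
#' the POD count (100000) and quantiles (0.99, 0.999), the simulation
#' regime (16 localities x 9 individuals x 5000 loci at mean depth 16x),
#' and the global seed. The configuration round-trips losslessly through
#' YAML ([write_config()] / [read_config()]).
#'
#' @param ... overrides of any default, by name.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = c("simulate", "genotype", "diagnose", "diversity",
               "structure", "ibd_ibe", "scan"),
    # simulation regime
    n_localities = 16L, n_per_pop = 9L, n_loci = 5000L,
    extent_km = 500, n_covariates = 3L, covariate_sd = 0.5,
    base_sd = 0.5, ibd_range = 200, n_adaptive = 0L, effect_size = 0,
    covariate_name = "BIO12",
    mode = "tetrasomic", subgenome_divergence = 0,
    mean_depth = 16, depth_dispersion = 8, error_rate = 0.005,
    # genotype filters
    min_depth = 5L, max_missing = 0.10, maf_min = 0.05, min_carriers = 2L,
    # diversity
    locus_length_bp = 94L,
    # ibd/ibe
    collinearity_cutoff = 0.9, n_top_covariates = 3L,
    mantel_perms = 999L, mmrr_perms = 1000L,
    # scan
    pod_count = 100000L, pod_quantiles = c(0.99, 0.999),
    omega_shrink = 0.05)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a `"pipeline_config"`.
#' @param path YAML file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

# per-stage seeds fanned out from the global seed by a fixed counter
# scheme, so toggling one stage does not perturb another's randomness
stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 0L, genotype = 100L, diagnose = 200L,
               diversity = 300L, structure = 400L, ibd_ibe = 500L,
               scan = 600L)
  as.integer(cfg$seed) * 1000L + offsets[[stage]]
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order on a simulated dataset
#' (or a dataset directory produced earlier), writing each stage's outputs
#' plus a manifest with parameters, seeds and content hashes. Reruns with
#' an identical configuration are bit-identical.
#'
#' @param cfg a `"pipeline_config"`.
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  log_line <- function(...) message(sprintf(...))

  if ("simulate" %in% cfg$stages) {
    log_line("[simulate] %d localities x %d ind x %d loci",
             cfg$n_localities, cfg$n_per_pop, cfg$n_loci)
    truth <- simulate_dataset(
      n_localities = cfg$n_localities, n_per_pop = cfg$n_per_pop,
      n_loci = cfg$n_loci, extent_km = cfg$extent_km,
      n_covariates = cfg$n_covariates, covariate_sd = cfg$covariate_sd,
      base_sd = cfg$base_sd, ibd_range = cfg$ibd_range,
      n_adaptive = cfg$n_adaptive, effect_size = cfg$effect_size,
      covariate_name = cfg$covariate_name, mode = cfg$mode,
      subgenome_divergence = cfg$subgenome_divergence,
      mean_depth = cfg$mean_depth, depth_dispersion = cfg$depth_dispersion,
      error_rate = cfg$error_rate, seed = stage_seed(cfg, "simulate"))
    write_simulated_dataset(truth, file.path(out_dir, "simulated"))
    res$truth <- truth
  }

  if ("genotype" %in% cfg$stages) {
    if (is.null(res$truth)) stop("genotype stage needs the simulate stage")
    log_line("[genotype] calling dosages (min_depth=%d)", cfg$min_depth)
    res$calls <- call_genotypes(res$truth$reads, min_depth = cfg$min_depth,
                                max_missing = cfg$max_missing,
                                maf_min = cfg$maf_min,
                                min_carriers = cfg$min_carriers)
    write_genotypes(res$calls, res$truth$reads,
                    file.path(out_dir, "genotypes"))
  }

  membership <- if (!is.null(res$truth)) res$truth$membership else NULL

  if ("diagnose" %in% cfg$stages) {
    log_line("[diagnose] inheritance mode")
    prof <- genotype_frequency_profile(res$calls)
    res$inheritance <- classify_inheritance(prof)
    res$het_balance_D <- heterozygote_balance(res$calls)
    write_profile_tsv(prof, file.path(out_dir, "inheritance_profile.tsv"))
    writeLines(sprintf("label\t%s\nscore\t%.6f\nD\t%.6f",
                       res$inheritance$label, res$inheritance$score,
                       res$het_balance_D),
               file.path(out_dir, "inheritance.tsv"))
  }

  if ("diversity" %in% cfg$stages) {
    log_line("[diversity] per-locality summaries and F_ST")
    region <- stats::setNames(res$truth$pops$region, res$truth$pops$locality)
    res$diversity <- diversity_summary(res$calls, membership,
                                       locus_length_bp = cfg$locus_length_bp,
                                       region = region)
    res$fst <- pairwise_fst(res$calls, membership)
    utils::write.table(res$diversity, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(res$fst, file.path(out_dir, "fst.tsv"), "locality")
    write_matrix_tsv(linearize_fst(res$fst),
                     file.path(out_dir, "fst_linearized.tsv"), "locality")
  }

  if ("structure" %in% cfg$stages) {
    log_line("[structure] relatedness and PCA")
    res$relatedness <- relatedness_matrix(res$calls)
    res$pca <- pca_dosage(res$calls, n_components = 3)
    write_matrix_tsv(res$relatedness, file.path(out_dir, "relatedness.tsv"),
                     "individual")
    write_matrix_tsv(res$pca$scores, file.path(out_dir, "pca_scores.tsv"),
                     "individual")
    utils::write.table(
      data.frame(component = seq_along(res$pca$explained_pct),
                 explained_pct = res$pca$explained_pct),
      file.path(out_dir, "pca_explained.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("ibd_ibe" %in% cfg$stages) {
    log_line("[ibd_ibe] Mantel, MMRR, commonality")
    pops <- res$truth$pops
    covs <- covariate_table(pops)
    kept <- prune_collinear(covs, cfg$collinearity_cutoff)
    gen <- linearize_fst(res$fst)[pops$locality, pops$locality]
    top <- rank_covariates(gen, covs[, kept, drop = FALSE],
                           cfg$n_top_covariates)
    geo <- geographic_distance(pops, log_transform = TRUE)
    env <- environmental_distance(covs, top$covariate)
    s <- stage_seed(cfg, "ibd_ibe")
    res$ibd_ibe <- list(
      covariates_kept = kept, covariates_top = top,
      mantel_geo = mantel_test(gen, geo, cfg$mantel_perms, seed = s),
      mantel_env = mantel_test(gen, env, cfg$mantel_perms, seed = s + 1L),
      partial_geo = partial_mantel_test(gen, geo, env, cfg$mantel_perms,
                                        seed = s + 2L),
      partial_env = partial_mantel_test(gen, env, geo, cfg$mantel_perms,
                                        seed = s + 3L),
      mmrr = mmrr(gen, list(GEO = geo, ENV = env), cfg$mmrr_perms,
                  seed = s + 4L),
      commonality = commonality_two(gen, geo, env))
    m <- res$ibd_ibe
    tab <- data.frame(
      statistic = c("mantel_geo_r", "mantel_geo_p", "mantel_env_r",
                    "mantel_env_p", "partial_geo_r", "partial_geo_p",
                    "partial_env_r", "partial_env_p", "mmrr_r2",
                    "mmrr_beta_geo", "mmrr_beta_env", "commonality_unique_geo",
                    "commonality_unique_env", "commonality_common"),
      value = c(m$mantel_geo$r, m$mantel_geo$p, m$mantel_env$r,
                m$mantel_env$p, m$partial_geo$r, m$partial_geo$p,
                m$partial_env$r, m$partial_env$p, m$mmrr$r_squared,
                m$mmrr$betas["GEO"], m$mmrr$betas["ENV"],
                m$commonality$unique[1], m$commonality$unique[2],
                m$commonality$common))
    utils::write.table(tab, file.path(out_dir, "ibd_ibe.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("scan" %in% cfg$stages) {
    log_line("[scan] XtX + association with %d PODs", cfg$pod_count)
    covs <- covariate_table(res$truth$pops)
    res$scan <- selection_scan(res$calls, membership, covs,
                               n_pods = cfg$pod_count,
                               shrink = cfg$omega_shrink,
                               seed = stage_seed(cfg, "scan"))
    utils::write.table(res$scan$table, file.path(out_dir, "scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(res$scan$omega, file.path(out_dir, "omega.tsv"), "pop")
    jsonlite::write_json(res$scan$thresholds,
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # manifest: parameters, seeds, content hashes of every written file
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    config = unclass(cfg),
    stage_seeds = lapply(stats::setNames(nm = cfg$stages),
                         function(s) stage_seed(cfg, s)),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    sub(paste0("^", out_dir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- file.path(out_dir, "manifest.json")
  invisible(res)
}
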