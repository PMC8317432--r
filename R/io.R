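#' Write a simulated dataset to disk
#'
#' Writes a VCF 4.2 (biallelic SNPs, one sample column per individual,
#' per-sample `AD` = ref,alt and `DP`; per-site other-read totals in the
#' `OTH` INFO field), the per-cell other-read counts as a TSV (the VCF AD
#' field holds only ref/alt, so the third-allele counts travel alongside),
#' the truth tables (population frequencies, dosages, adaptive flags) and
#' the locality metadata CSV (`locality,region,lat,lon,<covariate...>`).
#'
#' @param truth a `"sim_truth"` object with reads attached
#'   (see [simulate_dataset()]).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_simulated_dataset <- function(truth, out_dir) {
  reads <- truth$reads
  if (is.null(reads)) stop("truth has no read counts; run simulate_read_counts()")
  if (!all(dim(reads$ref) == dim(truth$dosage)))
    stop("read-count and dosage dimensions disagree")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- c(vcf = file.path(out_dir, "reads.vcf"),
             other = file.path(out_dir, "other_counts.tsv"),
             freq = file.path(out_dir, "truth_freq.tsv"),
             dosage = file.path(out_dir, "truth_dosage.tsv"),
             sites = file.path(out_dir, "truth_sites.tsv"),
             pops = file.path(out_dir, "populations.csv"))

  write_read_vcf(reads, files["vcf"])
  write_matrix_tsv(reads$other, files["other"], id_col = "individual")
  write_matrix_tsv(truth$freq, files["freq"], id_col = "site")
  write_matrix_tsv(truth$dosage, files["dosage"], id_col = "individual")
  utils::write.table(
    data.frame(site = rownames(truth$freq), adaptive = truth$adaptive),
    files["sites"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(truth$pops, files["pops"], row.names = FALSE, quote = FALSE)
  invisible(files)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write read counts as a ploidy-aware VCF
#'
#' @param reads a `"read_counts"` object.
#' @param path output path (`.vcf`).
#' @param gt optional dosage matrix (individuals x sites, NA = missing) to
#'   encode as ploidy-4 GT strings (e.g. `0/0/1/1`); by default GT is
#'   missing (`./././.`).
#' @return `path`, invisibly.
#' @export
write_read_vcf <- function(reads, path, gt = NULL) {
  n <- nrow(reads$ref); L <- ncol(reads$ref)
  ids <- rownames(reads$ref)
  sites <- colnames(reads$ref)
  if (is.null(sites)) sites <- sprintf("site_%05d", seq_len(L))
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(n))

  meta <- c("##fileformat=VCFv4.2",
            "##source=tetrapop",
            "##INFO=<ID=OTH,Number=1,Type=Integer,Description=\"Total reads matching neither allele at this site\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depths for ref and alt alleles\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", ids), collapse = "\t")

  oth_tot <- colSums(reads$other)
  gt_str <- if (is.null(gt)) {
    matrix("./././.", n, L)
  } else {
    dosage_to_gt(gt)
  }
  dp <- reads$ref + reads$alt + reads$other
  cell <- matrix(paste0(gt_str, ":", reads$ref, ",", reads$alt, ":", dp),
                 n, L)
  body <- vapply(seq_len(L), function(l) {
    paste(c(sites[l], "47", sites[l], "C", "T", ".", "PASS",
            paste0("OTH=", oth_tot[l]), "GT:AD:DP", cell[, l]),
          collapse = "\t")
  }, character(1))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' Encode a dosage matrix as ploidy-4 GT strings
#'
#' @param dosage individuals x sites matrix in 0..4, NA = missing.
#' @return character matrix of the same shape (`0/1/1/1`-style).
#' @export
dosage_to_gt <- function(dosage) {
  codes <- c("0/0/0/0", "0/0/0/1", "0/0/1/1", "0/1/1/1", "1/1/1/1")
  out <- matrix("./././.", nrow(dosage), ncol(dosage),
                dimnames = dimnames(dosage))
  ok <- !is.na(dosage)
  out[ok] <- codes[dosage[ok] + 1L]
  out
}

#' Read a dataset written by [write_simulated_dataset()]
#'
#' Reconstructs the read-count matrices from the VCF `AD`/`DP` fields plus
#' the other-count TSV, and reloads the truth tables and locality metadata.
#'
#' @param dir dataset directory.
#' @return A list with `reads` (a `"read_counts"` object), `freq`, `dosage`,
#'   `adaptive`, and `pops`.
#' @export
read_simulated_dataset <- function(dir) {
  reads <- read_read_vcf(file.path(dir, "reads.vcf"))
  other <- read_matrix_tsv(file.path(dir, "other_counts.tsv"))
  storage.mode(other) <- "integer"
  reads$other <- other[rownames(reads$ref), colnames(reads$ref)]
  freq <- read_matrix_tsv(file.path(dir, "truth_freq.tsv"))
  dosage <- read_matrix_tsv(file.path(dir, "truth_dosage.tsv"))
  storage.mode(dosage) <- "integer"
  sites <- utils::read.delim(file.path(dir, "truth_sites.tsv"))
  pops <- utils::read.csv(file.path(dir, "populations.csv"),
                          stringsAsFactors = FALSE)
  list(reads = reads, freq = freq, dosage = dosage,
       adaptive = sites$adaptive, pops = pops)
}

#' Read per-sample allele depths from a VCF into read-count matrices
#'
#' Uses vcfR to parse the VCF; records must be biallelic SNPs with a
#' per-sample `AD` field. Per-site other-read totals are taken from the
#' `OTH` INFO field when present (spread is not attempted: the per-cell
#' `other` matrix is zero unless set by the caller).
#'
#' @param path VCF path.
#' @return A `"read_counts"` object (individuals x sites matrices).
#' @export
read_read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  ref <- t(apply(ad, 1, function(x) as.integer(sub(",.*", "", x))))
  alt <- t(apply(ad, 1, function(x) as.integer(sub(".*,", "", x))))
  dimnames(ref) <- dimnames(alt) <- dimnames(ad)
  # vcfR returns sites x individuals; transpose to individuals x sites
  ref <- t(ref); alt <- t(alt)
  ref[is.na(ref)] <- 0L; alt[is.na(alt)] <- 0L
  structure(list(ref = ref, alt = alt,
                 other = matrix(0L, nrow(ref), ncol(ref),
                                dimnames = dimnames(ref))),
            class = "read_counts")
}

#' Read a locality metadata table
#'
#' Expects the CSV layout `locality,region,lat,lon,<covariate...>`.
#'
#' @param path CSV path.
#' @return data.frame in the [simulate_landscape()] layout.
#' @export
read_population_table <- function(path) {
  pops <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locality", "region", "lat", "lon")
  if (!all(need %in% names(pops)))
    stop("population table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(pops$locality)) stop("duplicate locality ids")
  pops
}

#' Validate a VCF + locality-table input pair
#'
#' Checks that VCF records are biallelic SNPs carrying `AD`, that VCF sample
#' names agree with the metadata localities (sample names are expected to be
#' `<locality>_<k>`), and that coordinates are in range. Problems are
#' collected, not thrown, so a partially valid input can be inspected.
#'
#' @param vcf_path path to a VCF with per-sample AD.
#' @param pops_path path to the locality CSV.
#' @return A list with `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(vcf_path, pops_path) {
  problems <- character()
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    problems <- c(problems, sprintf(
      "%d multiallelic record(s) rejected (e.g. %s)",
      sum(multi), fix[which(multi)[1], "ID"]))
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("AD", fmt)))
    problems <- c(problems, "AD field missing from FORMAT in some records")

  pops <- tryCatch(read_population_table(pops_path), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  if (!is.null(pops)) {
    if (any(pops$lat < -90 | pops$lat > 90) ||
        any(pops$lon < -180 | pops$lon > 180))
      problems <- c(problems, "coordinates out of range")
    samples <- colnames(v@gt)[-1]
    sample_loc <- sub("_[0-9]+$", "", samples)
    orphan <- setdiff(sample_loc, pops$locality)
    if (length(orphan))
      problems <- c(problems, paste0(
        "VCF samples with no metadata locality: ",
        paste(unique(orphan), collapse = ", ")))
  }
  list(ok = length(problems) == 0, problems = problems)
}
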