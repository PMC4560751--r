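#' Read a genotype matrix from a minimal VCF
#'
#' Reads a VCF 4.x file with per-sample `GT` and `DP` FORMAT fields into a
#' [genotype_matrix()]. Only those two keys are interpreted; other FORMAT
#' keys are ignored. Records must be biallelic: multi-allelic records must
#' be decomposed upstream (e.g. `bcftools norm -m-`).
#'
#' `./.` (or `.`) genotypes map to missing; an absent or missing `DP` maps
#' to depth 0. Phased separators (`|`) are accepted and treated as unphased.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return A `genotype_matrix`. Site metadata columns `is_known`,
#'   `functional_category`, `repeat_class` are filled with defaults; use
#'   [annotate_sites()] to attach annotations.
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  check_vcf_lines(path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  n_sites <- nrow(fix)
  samples <- colnames(v@gt)[-1] %||% character(0)
  if (n_sites > 0 && any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic record(s) found; decompose the VCF first ",
         "(e.g. 'bcftools norm -m-')", call. = FALSE)
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )[seq_len(n_sites), , drop = FALSE]
  if (n_sites == 0 || length(samples) == 0) {
    gt <- matrix(NA_integer_, n_sites, length(samples))
    dp <- matrix(0L, n_sites, length(samples))
    return(genotype_matrix(gt, dp, sites, samples))
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp_chr <- suppressWarnings(vcfR::extract.gt(v, element = "DP"))
  gt <- decode_gt(gt_chr)
  dp <- matrix(suppressWarnings(as.integer(dp_chr)), nrow = n_sites)
  dp[is.na(dp)] <- 0L
  genotype_matrix(gt, dp, sites, samples)
}

# light structural scan so malformed body lines are reported by line number
check_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  ln <- 0L
  n_cols <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0) break
    ln <- ln + 1L
    if (startsWith(line, "##")) next
    if (startsWith(line, "#CHROM")) {
      n_cols <- length(strsplit(line, "\t", fixed = TRUE)[[1]])
      if (n_cols < 8) stop("malformed VCF header line ", ln, call. = FALSE)
      next
    }
    if (is.na(n_cols)) stop("VCF lacks a #CHROM header line", call. = FALSE)
    nf <- length(strsplit(line, "\t", fixed = TRUE)[[1]])
    if (nf != n_cols)
      stop(sprintf("malformed VCF line %d: %d fields, expected %d",
                   ln, nf, n_cols), call. = FALSE)
  }
  invisible(TRUE)
}

decode_gt <- function(gt_chr) {
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  out <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr))
  out[gt_chr %in% c("0/0", "0")] <- 0L
  out[gt_chr %in% c("0/1", "1/0")] <- 1L
  out[gt_chr %in% c("1/1", "1")] <- 2L
  bad <- !is.na(gt_chr) & !(gt_chr %in% c("0/0", "0/1", "1/0", "1/1",
                                          "./.", ".", "0", "1"))
  if (any(bad))
    stop("unsupported genotype token(s): ",
         paste(unique(gt_chr[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits `GT:DP` per sample; missing genotypes are written as `./.`.
#' Round-trips with [read_genotype_vcf()] on genotype and depth content.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (plain text).
#' @return Invisibly, `path`.
#' @export
write_genotype_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(gm$genotype) > 0) {
    gt_tok <- matrix(c("0/0", "0/1", "1/1")[gm$genotype + 1L],
                     nrow = nrow(gm$genotype))
    gt_tok[is.na(gm$genotype)] <- "./."
    cell <- matrix(paste0(gt_tok, ":", gm$depth), nrow = nrow(gt_tok))
    body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                  gm$sites$alt, ".", "PASS", ".", "GT:DP",
                  apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read named regions from a BED4 file
#'
#' BED input is 0-based half-open; regions are held internally as 1-based
#' inclusive intervals (a `GRanges`), so a BED line
#' `chr1 104209999 104211500 RegionX` becomes `chr1:104210000-104211500`
#' with width 1501.
#'
#' @param path Path to a 4-column BED file (chrom, start, end, name).
#' @return A `GRanges` with one region per row, named by the BED name column.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("BED file must carry a name in column 4", call. = FALSE)
  if (any(IRanges::width(gr) < 1))
    stop("zero-length region(s) in BED file", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate region names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(gr) <- nm
  gr
}

#' Read a site annotation table
#'
#' Tab-separated with header `chrom pos ref alt category repeat_class known`.
#'
#' @param path File path.
#' @return Data frame ready for [annotate_sites()].
#' @export
read_annotation_table <- function(path) {
  an <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "category", "repeat_class", "known")
  missing_cols <- setdiff(required, names(an))
  if (length(missing_cols))
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  an$known <- as.logical(an$known)
  an
}

#' Read array-truth genotypes from a site x sample table
#'
#' Tab-separated; first column `site` holds `chrom:pos:ref:alt` keys,
#' remaining columns are samples with genotype codes 0/1/2 or NA.
#'
#' @param path File path.
#' @return An [array_truth()] whose rows are keyed by site.
#' @export
read_array_truth <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "site")
    stop("first column of an array-truth table must be 'site'", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$site
  array_truth(m, colnames(m))
}

#' Read per-sample per-region mean depths
#'
#' Tab-separated; first column `sample`, remaining columns one per named
#' region, values are mean per-base read depth over the region.
#'
#' @param path File path.
#' @return A `region_depth_profile` (see [region_depth_profile()]).
#' @export
read_region_depths <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample")
    stop("first column of a region-depth table must be 'sample'", call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$sample
  region_depth_profile(m)
}

#' Run configuration with the pipeline's default thresholds
#'
#' Collects every tunable threshold of the filter cascade and the SFS
#' analysis in one validated list. Values mirror the pipeline defaults:
#' per-depth-bin precision > 0.998 retained, repeat-class precision <= 0.997
#' removed, locus missingness > 10% removed, Hardy-Weinberg exact p < 1e-5
#' removed, MAF bin edges 0.1% / 0.5% / 5%, projection to 90% of the cohort.
#'
#' @param depth_precision_min Per-sample depth-bin precision retention
#'   threshold (strict `>`).
#' @param repeat_precision_min Repeat-class precision threshold (classes at
#'   or below it are removed).
#' @param max_missing Maximum tolerated missing-genotype fraction per site
#'   (strict `>` removal).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level.
#' @param maf_very_rare,maf_rare,maf_low Upper bounds (inclusive) of the
#'   very-rare, rare and low-frequency minor-allele-frequency bins.
#' @param projection_fraction Fraction of the cohort used as the uniform
#'   projection sample size.
#' @param min_bin_sites Minimum array-truth calls per depth bin before
#'   merging with the nearest lower bin.
#' @param depth_cap Depth above which bins are pooled.
#' @param seed Non-negative integer seed.
#' @param paths Optional named list of file paths.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(depth_precision_min = 0.998,
                       repeat_precision_min = 0.997,
                       max_missing = 0.10,
                       hwe_alpha = 1e-5,
                       maf_very_rare = 0.001,
                       maf_rare = 0.005,
                       maf_low = 0.05,
                       projection_fraction = 0.90,
                       min_bin_sites = 200,
                       depth_cap = 150,
                       seed = 1L,
                       paths = list()) {
  cfg <- list(
    depth_precision_min = depth_precision_min,
    repeat_precision_min = repeat_precision_min,
    max_missing = max_missing,
    hwe_alpha = hwe_alpha,
    maf_very_rare = maf_very_rare,
    maf_rare = maf_rare,
    maf_low = maf_low,
    projection_fraction = projection_fraction,
    min_bin_sites = as.integer(min_bin_sites),
    depth_cap = as.integer(depth_cap),
    seed = as.integer(seed),
    paths = paths
  )
  for (nm in c("depth_precision_min", "repeat_precision_min", "max_missing",
               "hwe_alpha", "maf_very_rare", "maf_rare", "maf_low",
               "projection_fraction")) {
    assert_fraction(cfg[[nm]], nm)
    if (cfg[[nm]] <= 0 && nm != "max_missing")
      stop(sprintf("'%s' must be in (0, 1]", nm), call. = FALSE)
  }
  if (cfg$seed < 0) stop("seed must be non-negative", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read a JSON run configuration
#'
#' Unknown keys are rejected; absent keys take the [run_config()] defaults.
#'
#' @param path Path to a JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}
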