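#' Construct a genotype matrix
#'
#' The central container every filter transforms: diploid genotype codes and
#' per-cell read depth for a set of variant sites across a cohort. Genotypes
#' are coded 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate) and `NA` (missing / not genotyped). Depth is the number of
#' aligned reads covering the site in that sample (reads of mapping quality
#' >= 5 upstream of this package).
#'
#' @param genotype Integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param depth Non-negative integer matrix of the same shape.
#' @param sites Data frame of per-site metadata with at least columns
#'   `chrom`, `pos`, `ref`, `alt`; optionally `is_known`,
#'   `functional_category`, `repeat_class`, `chromatin_state`.
#' @param samples Character vector of sample identifiers (one per column).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotype, depth, sites, samples) {
  genotype <- as.matrix(genotype)
  depth <- as.matrix(depth)
  storage.mode(genotype) <- "integer"
  storage.mode(depth) <- "integer"
  if (!identical(dim(genotype), dim(depth)))
    stop("genotype and depth must have identical dimensions", call. = FALSE)
  if (nrow(genotype) != nrow(sites))
    stop("sites metadata must have one row per genotype row", call. = FALSE)
  if (ncol(genotype) != length(samples))
    stop("one sample id per genotype column required", call. = FALSE)
  if (any(!is.na(genotype) & !(genotype %in% GT_CODES)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (any(depth < 0, na.rm = TRUE))
    stop("depths must be non-negative", call. = FALSE)
  sites <- normalize_sites(sites)
  dimnames(genotype) <- dimnames(depth) <- list(site_keys(sites), samples)
  structure(
    list(genotype = genotype, depth = depth, sites = sites,
         samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

normalize_sites <- function(sites) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols))
    stop("sites table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(sites$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  if (any(sites$ref == sites$alt))
    stop("ref and alt alleles must differ", call. = FALSE)
  n <- nrow(sites)
  if (is.null(sites$is_known)) sites$is_known <- rep(FALSE, n)
  if (is.null(sites$functional_category))
    sites$functional_category <- rep("other", n)
  if (is.null(sites$repeat_class)) sites$repeat_class <- rep("none", n)
  if (is.null(sites$chromatin_state))
    sites$chromatin_state <- rep(NA_character_, n)
  bad_cat <- setdiff(unique(sites$functional_category), FUNCTIONAL_CATEGORIES)
  if (length(bad_cat))
    stop("unknown functional_category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  bad_rep <- setdiff(unique(sites$repeat_class), REPEAT_CLASSES)
  if (length(bad_rep))
    stop("unknown repeat_class: ", paste(bad_rep, collapse = ", "),
         call. = FALSE)
  rownames(sites) <- NULL
  sites
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples\n",
              nrow(x$genotype), length(x$samples)))
  cat(sprintf("  missing genotypes: %.2f%%\n",
              100 * mean(is.na(x$genotype))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotype)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm A [genotype_matrix()].
#' @param sites Logical or integer index over rows (sites).
#' @param samples Logical, integer, or character index over columns.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_matrix <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(sites)) seq_len(nrow(gm$genotype)) else sites
  sj <- if (is.null(samples)) seq_along(gm$samples) else samples
  if (is.character(sj)) sj <- match(sj, gm$samples)
  genotype_matrix(
    gm$genotype[si, sj, drop = FALSE],
    gm$depth[si, sj, drop = FALSE],
    gm$sites[si, , drop = FALSE],
    gm$samples[sj]
  )
}

#' SNP-array truth genotypes aligned to a genotype matrix
#'
#' A sparse overlay of externally genotyped calls (SNP array) used as truth
#' for concordance calibration. Cells not assayed by the array are `NA`.
#'
#' @param genotype Integer matrix, same shape and dimnames convention as the
#'   companion genotype matrix; `NA` marks cells without array data.
#' @param sample_ids Character vector of sample ids (columns).
#' @return Object of class `array_truth`.
#' @export
array_truth <- function(genotype, sample_ids) {
  genotype <- as.matrix(genotype)
  storage.mode(genotype) <- "integer"
  if (any(!is.na(genotype) & !(genotype %in% GT_CODES)))
    stop("array truth codes must be 0, 1, 2 or NA", call. = FALSE)
  if (ncol(genotype) != length(sample_ids))
    stop("one sample id per column required", call. = FALSE)
  colnames(genotype) <- sample_ids
  structure(list(genotype = genotype, samples = as.character(sample_ids)),
            class = "array_truth")
}

#' @export
print.array_truth <- function(x, ...) {
  cat(sprintf("<array_truth> %d sites x %d samples, %d assayed cells\n",
              nrow(x$genotype), length(x$samples), sum(!is.na(x$genotype))))
  invisible(x)
}

# align truth overlay rows to a genotype matrix (by row key when named)
align_truth <- function(gm, truth) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(truth, "array_truth"))
  tg <- truth$genotype
  if (!is.null(rownames(tg)) && !is.null(rownames(gm$genotype))) {
    idx <- match(rownames(gm$genotype), rownames(tg))
    out <- matrix(NA_integer_, nrow(gm$genotype), ncol(tg))
    keep <- !is.na(idx)
    out[keep, ] <- tg[idx[keep], , drop = FALSE]
    colnames(out) <- colnames(tg)
    tg <- out
  } else if (nrow(tg) != nrow(gm$genotype)) {
    stop("array truth is not aligned to the genotype matrix", call. = FALSE)
  }
  sj <- match(gm$samples, truth$samples)
  out <- matrix(NA_integer_, nrow(gm$genotype), length(gm$samples))
  keep <- !is.na(sj)
  out[, keep] <- tg[, sj[keep], drop = FALSE]
  dimnames(out) <- dimnames(gm$genotype)
  out
}

#' Join site annotations onto a genotype matrix
#'
#' Annotations (functional category, repeat class, known/novel flag) are
#' produced upstream by annotation tools; here they are consumed as a table
#' and joined by the `(chrom, pos, ref, alt)` site key. Sites without a
#' matching annotation row fall back to `functional_category = "other"`,
#' `repeat_class = "none"`, `is_known = FALSE`, with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param annotation Data frame with columns
#'   `chrom, pos, ref, alt, category, repeat_class, known`.
#' @return The genotype matrix with site metadata replaced by the join.
#' @export
annotate_sites <- function(gm, annotation) {
  stopifnot(inherits(gm, "genotype_matrix"))
  key_gm <- site_keys(gm$sites)
  key_an <- paste(annotation$chrom, annotation$pos, annotation$ref,
                  annotation$alt, sep = ":")
  idx <- match(key_gm, key_an)
  unmatched <- sum(is.na(idx))
  if (unmatched > 0)
    warning(sprintf(
      "%d site(s) without annotation; defaulting to (other, none, novel)",
      unmatched), call. = FALSE)
  sites <- gm$sites
  hit <- !is.na(idx)
  sites$functional_category[hit] <- annotation$category[idx[hit]]
  sites$functional_category[!hit] <- "other"
  sites$repeat_class[hit] <- annotation$repeat_class[idx[hit]]
  sites$repeat_class[!hit] <- "none"
  sites$is_known[hit] <- as.logical(annotation$known[idx[hit]])
  sites$is_known[!hit] <- FALSE
  genotype_matrix(gm$genotype, gm$depth, sites, gm$samples)
}
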