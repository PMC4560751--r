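#' Per-sample, per-region mean depth profile
#'
#' Container for read-depth copy-number estimation over named regions. The
#' region set must include a diploid normalisation reference region
#' (`"RegionZ"` by default), chosen upstream for reference-genome
#' mappability, whose depth anchors each sample's diploid coverage.
#'
#' @param depths Numeric matrix, samples x regions, mean per-base depth;
#'   row names are sample ids, column names region names.
#' @param reference_region Name of the diploid reference region.
#' @return Object of class `region_depth_profile`.
#' @export
region_depth_profile <- function(depths, reference_region = "RegionZ") {
  depths <- as.matrix(depths)
  if (is.null(rownames(depths)) || is.null(colnames(depths)))
    stop("depth matrix needs sample row names and region column names",
         call. = FALSE)
  if (any(depths < 0)) stop("depths must be non-negative", call. = FALSE)
  if (!(reference_region %in% colnames(depths)))
    stop("reference region '", reference_region, "' absent from profile",
         call. = FALSE)
  structure(list(depths = depths, reference_region = reference_region),
            class = "region_depth_profile")
}

#' @export
print.region_depth_profile <- function(x, ...) {
  cat(sprintf("<region_depth_profile> %d samples x %d regions (reference %s)\n",
              nrow(x$depths), ncol(x$depths), x$reference_region))
  invisible(x)
}

#' Normalised diploid copy number of a region
#'
#' Divides the region's mean depth by half the reference-region depth, so
#' that diploid regions read 2. Scale-invariant to a sample's global
#' coverage. Samples with zero reference depth yield `NA` with a warning.
#'
#' @param profile A [region_depth_profile()].
#' @param region Region name.
#' @param samples Sample ids (default: all).
#' @return Named numeric vector of continuous diploid copy numbers.
#' @export
normalized_cn <- function(profile, region, samples = NULL) {
  stopifnot(inherits(profile, "region_depth_profile"))
  d <- profile$depths
  if (!(region %in% colnames(d)))
    stop("region '", region, "' absent from profile", call. = FALSE)
  if (is.null(samples)) samples <- rownames(d)
  ref <- d[samples, profile$reference_region]
  bad <- ref <= 0
  if (any(bad)) {
    warning("zero reference depth; excluding sample(s): ",
            paste(samples[bad], collapse = ", "), call. = FALSE)
  }
  cn <- 2 * d[samples, region] / ref
  cn[bad] <- NA_real_
  setNames(cn, samples)
}

#' Summed amylase copy number and unit-region copy number
#'
#' For each sample, `y` is the summed normalised diploid copy number over
#' the three AMY1 gene regions (AMY1A, AMY1B, AMY1C — too similar to
#' resolve individually from short reads) and `n` is the normalised copy
#' number of the inter-gene unit region (Region X). Under the diplotype
#' unit model these satisfy `y = 2n + 2`.
#'
#' @param profile A [region_depth_profile()] containing regions `AMY1A`,
#'   `AMY1B`, `AMY1C`, `RegionX` and the reference region.
#' @param samples Sample ids (default: all).
#' @return Data frame with columns `sample`, `y`, `n`.
#' @export
amy1_cn <- function(profile, samples = NULL) {
  stopifnot(inherits(profile, "region_depth_profile"))
  needed <- c("AMY1A", "AMY1B", "AMY1C", "RegionX")
  absent <- setdiff(needed, colnames(profile$depths))
  if (length(absent))
    stop("profile lacks region(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  if (is.null(samples)) samples <- rownames(profile$depths)
  y <- normalized_cn(profile, "AMY1A", samples) +
       normalized_cn(profile, "AMY1B", samples) +
       normalized_cn(profile, "AMY1C", samples)
  n <- normalized_cn(profile, "RegionX", samples)
  data.frame(sample = samples, y = unname(y), n = unname(n),
             stringsAsFactors = FALSE)
}

#' Fit the diplotype unit model by least squares
#'
#' Ordinary least squares of the summed gene copy number `y` on the unit
#' region copy number `n`, with 95% parameter intervals and a flag for
#' whether the unit model `y = 2n + 2` (slope 2, intercept 2) lies within
#' them.
#'
#' @param pairs Data frame with columns `n` and `y` (one row per sample).
#' @return List of class `unit_model_fit`: `slope`, `intercept`,
#'   `residual_sd`, `ci` (2x2 matrix), `consistent_with_unit_model`, `fit`
#'   (the underlying `lm`).
#' @export
fit_unit_model <- function(pairs) {
  pairs <- pairs[stats::complete.cases(pairs[, c("n", "y")]), , drop = FALSE]
  if (length(unique(pairs$n)) < 2)
    stop("rank deficient: unit-region copy number does not vary",
         call. = FALSE)
  fit <- lm(y ~ n, data = pairs)
  ci <- confint(fit, level = 0.95)
  rownames(ci) <- c("intercept", "slope")
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ok <- ci["slope", 1] <= 2 && 2 <= ci["slope", 2] &&
        ci["intercept", 1] <= 2 && 2 <= ci["intercept", 2]
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = summary(fit)$sigma, ci = ci,
                 consistent_with_unit_model = ok, fit = fit),
            class = "unit_model_fit")
}

#' @export
print.unit_model_fit <- function(x, ...) {
  cat(sprintf("<unit_model_fit> y = %.3f n + %.3f (residual sd %.3f)\n",
              x$slope, x$intercept, x$residual_sd))
  cat(sprintf("  unit model y = 2n + 2 within 95%% CIs: %s\n",
              x$consistent_with_unit_model))
  invisible(x)
}

#' Integer copy-number call from a continuous estimate
#'
#' Rounds half-up by default. With `parity = "even"` the call snaps to the
#' nearest even integer (the amylase copy unit is two genes, so summed
#' AMY1 diploid copies are even), resolving exact ties downward.
#'
#' @param cn Continuous copy-number estimate(s), >= 0.
#' @param parity `"none"` or `"even"`.
#' @return Integer vector of called copies.
#' @export
#' @examples
#' integer_cn_call(8.27)            # 8
#' integer_cn_call(7.0, "even")     # 6 (tie resolves down)
integer_cn_call <- function(cn, parity = c("none", "even")) {
  parity <- match.arg(parity)
  stopifnot(all(cn >= 0, na.rm = TRUE))
  out <- switch(parity,
    none = round_half_up(cn),
    even = round_even_tie_down(cn))
  as.integer(out)
}

#' Merge structural-variant calls overlapping reciprocally by at least 80%
#'
#' Pairs of intervals (1-based inclusive, one chromosome) whose reciprocal
#' overlap — overlap length divided by each interval's length — is at least
#' `min_overlap` are merged, transitively, into one unified call whose
#' start and end are the arithmetic means of the member starts and ends,
#' rounded half-up. The output is sorted by start, making the result
#' invariant to input order.
#'
#' @param calls Data frame with columns `start`, `end`.
#' @param min_overlap Reciprocal-overlap threshold, default 0.80.
#' @return Data frame `start`, `end`, `n_members`, sorted by start.
#' @export
merge_calls_80 <- function(calls, min_overlap = 0.80) {
  n <- nrow(calls)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0),
                                n_members = integer(0)))
  stopifnot(all(calls$end >= calls$start))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- min(calls$end[i], calls$end[j]) -
          max(calls$start[i], calls$start[j]) + 1
    if (ov <= 0) next
    len_i <- calls$end[i] - calls$start[i] + 1
    len_j <- calls$end[j] - calls$start[j] + 1
    if (ov / len_i >= min_overlap && ov / len_j >= min_overlap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  merged <- lapply(split(seq_len(n), root), function(idx) {
    data.frame(start = round_half_up(mean(calls$start[idx])),
               end = round_half_up(mean(calls$end[idx])),
               n_members = length(idx))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a structural-variant call as known or novel
#'
#' An insertion is known when its breakpoint lies within 10 bp of the
#' nearest catalogued insertion; a deletion is known when a catalogued
#' deletion covers at least 50% of the call's length (both thresholds
#' inclusive).
#'
#' @param call List or one-row data frame. For insertions: `type`
#'   (`"insertion"`) and `pos` (breakpoint). For deletions: `type`
#'   (`"deletion"`), `start`, `end`.
#' @param catalogue Data frame of known calls with columns `type`, `pos`
#'   (insertions), `start`, `end` (deletions).
#' @param max_ins_dist Insertion breakpoint distance bound, default 10.
#' @param min_del_overlap Deletion covered-fraction bound, default 0.50.
#' @return `"known"` or `"novel"`.
#' @export
classify_sv_novelty <- function(call, catalogue,
                                max_ins_dist = 10, min_del_overlap = 0.50) {
  type <- call$type
  if (!type %in% c("insertion", "deletion"))
    stop("call type must be 'insertion' or 'deletion'", call. = FALSE)
  cat_typed <- catalogue[catalogue$type == type, , drop = FALSE]
  if (nrow(cat_typed) == 0) return("novel")
  if (type == "insertion") {
    if (min(abs(cat_typed$pos - call$pos)) <= max_ins_dist) return("known")
    return("novel")
  }
  len <- call$end - call$start + 1
  ov <- pmax(0, pmin(cat_typed$end, call$end) -
                pmax(cat_typed$start, call$start) + 1)
  if (any(ov / len >= min_del_overlap)) "known" else "novel"
}

#' Shipped amylase-locus region definitions (hg19)
#'
#' The region set used for amylase copy-number estimation, as 1-based
#' inclusive hg19 intervals: the three AMY1 gene loci, AMY2B, the
#' inter-gene unit region (Region X), a control region (Region Y) and the
#' diploid normalisation reference (Region Z). The AMY1A interval follows
#' the published text even though it is much longer than the other two
#' gene loci and overlaps the AMY2B interval; supply your own BED via
#' [read_regions_bed()] if you prefer different definitions.
#'
#' @return Data frame: `region`, `chrom`, `start`, `end`.
#' @export
amylase_regions <- function() {
  data.frame(
    region = c("AMY2B", "AMY1A", "AMY1B", "AMY1C",
               "RegionX", "RegionY", "RegionZ"),
    chrom = "chr1",
    start = c(104096436L, 104096436L, 104230036L, 104293027L,
              104210000L, 104350000L, 104400000L),
    end = c(104122156L, 104207173L, 104239302L, 104301312L,
            104211500L, 104400000L, 104450000L),
    stringsAsFactors = FALSE
  )
}
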