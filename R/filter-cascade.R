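#' Per-sample genotype concordance against array truth, by read depth
#'
#' Groups a sample's variant calls by read depth and computes precision and
#' recall against SNP-array truth genotypes, the calibration underlying the
#' per-sample depth filter. A call counts toward precision when the
#' sequencing genotype is a variant (het or hom-alt) at a cell where the
#' array is non-missing; it is concordant when the genotypes are equal.
#' Recall counts array-variant cells recovered with the identical genotype.
#'
#' Depths are capped at `depth_cap` (deeper cells pool into the top bin).
#' Bins with fewer than `min_bin_sites` precision calls are merged into the
#' nearest lower bin before precision is computed; a deficient lowest bin is
#' merged upward so every reported bin meets the minimum when possible.
#'
#' @param gm A [genotype_matrix()].
#' @param truth An [array_truth()] overlay.
#' @param sample Sample identifier.
#' @param min_bin_sites Minimum precision calls per reported bin.
#' @param depth_cap Pooling cap for depth bins.
#' @return Data frame with one row per merged depth bin: `depth_lo`,
#'   `depth_hi`, `n_calls`, `n_concordant`, `precision`, `n_array_variant`,
#'   `n_recovered`, `recall` (precision/recall `NA` where undefined).
#' @export
depth_concordance <- function(gm, truth, sample,
                              min_bin_sites = 200, depth_cap = 150) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample: ", sample, call. = FALSE)
  tg_all <- if (inherits(truth, "array_truth")) align_truth(gm, truth) else
    truth   # pre-aligned matrix accepted internally
  tg <- tg_all[, j]
  if (!any(!is.na(tg)))
    stop("no overlapping array-truth cells for sample ", sample, call. = FALSE)
  ngs <- gm$genotype[, j]
  dp <- pmin(gm$depth[, j], as.integer(depth_cap))

  has_truth <- !is.na(tg)
  is_call <- has_truth & !is.na(ngs) & ngs >= 1L          # NGS variant call
  concord <- is_call & ngs == tg
  arr_var <- has_truth & tg >= 1L
  recover <- arr_var & !is.na(ngs) & ngs == tg

  depths <- sort(unique(dp[has_truth]))
  tab <- data.frame(
    depth_lo = depths, depth_hi = depths,
    n_calls = as.integer(tab_at(dp, is_call, depths)),
    n_concordant = as.integer(tab_at(dp, concord, depths)),
    n_array_variant = as.integer(tab_at(dp, arr_var, depths)),
    n_recovered = as.integer(tab_at(dp, recover, depths))
  )
  tab <- merge_depth_bins(tab, min_bin_sites)
  tab$precision <- ifelse(tab$n_calls > 0, tab$n_concordant / tab$n_calls, NA)
  tab$recall <- ifelse(tab$n_array_variant > 0,
                       tab$n_recovered / tab$n_array_variant, NA)
  tab$sample <- sample
  tab[, c("sample", "depth_lo", "depth_hi", "n_calls", "n_concordant",
          "precision", "n_array_variant", "n_recovered", "recall")]
}

tab_at <- function(dp, flag, depths) {
  counts <- tapply(flag, factor(dp, levels = depths), sum, default = 0L)
  as.vector(counts)
}

# merge bins below the call minimum into the nearest lower bin; a deficient
# bottom bin (no lower neighbour) merges upward instead
merge_depth_bins <- function(tab, min_bin_sites) {
  if (nrow(tab) <= 1) return(tab)
  i <- nrow(tab)
  while (i >= 2) {
    if (tab$n_calls[i] < min_bin_sites) {
      tab$depth_hi[i - 1] <- tab$depth_hi[i]
      for (f in c("n_calls", "n_concordant", "n_array_variant", "n_recovered"))
        tab[[f]][i - 1] <- tab[[f]][i - 1] + tab[[f]][i]
      tab <- tab[-i, , drop = FALSE]
    }
    i <- i - 1
  }
  while (nrow(tab) >= 2 && tab$n_calls[1] < min_bin_sites) {
    tab$depth_lo[2] <- tab$depth_lo[1]
    for (f in c("n_calls", "n_concordant", "n_array_variant", "n_recovered"))
      tab[[f]][2] <- tab[[f]][2] + tab[[f]][1]
    tab <- tab[-1, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Select the retained depth range for one sample
#'
#' Picks the longest contiguous run of depth bins whose precision strictly
#' exceeds `min_precision`; runs tie toward the one containing more calls.
#' Bins with no precision calls are excluded from consideration.
#'
#' @param table Output of [depth_concordance()] for one sample.
#' @param min_precision Retention threshold (strict), default 0.998.
#' @return List with `d_lo`, `d_hi` (inclusive depth bounds).
#' @export
select_depth_range <- function(table, min_precision = 0.998) {
  tab <- table[!is.na(table$precision), , drop = FALSE]
  if (nrow(tab) == 0)
    stop("sample uncalibratable: no depth bin with precision calls",
         call. = FALSE)
  pass <- tab$precision > min_precision
  if (!any(pass))
    stop("sample uncalibratable: no depth bin exceeds precision ",
         min_precision, call. = FALSE)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends)[r$values, , drop = FALSE]
  runs$len <- runs$end - runs$start + 1
  runs$calls <- mapply(function(s, e) sum(tab$n_calls[s:e]),
                       runs$start, runs$end)
  best <- runs[order(-runs$len, -runs$calls), ][1, ]
  list(d_lo = tab$depth_lo[best$start], d_hi = tab$depth_hi[best$end])
}

#' Calibrate per-sample depth ranges against array truth
#'
#' Runs [depth_concordance()] and [select_depth_range()] for every sample.
#' Samples with no passing depth bin are flagged uncalibratable and are
#' dropped from the cohort by [run_cascade()].
#'
#' @inheritParams depth_concordance
#' @param min_precision Retention threshold for [select_depth_range()].
#' @return Data frame: `sample`, `d_lo`, `d_hi`, `excluded` (logical).
#' @export
calibrate_depth_ranges <- function(gm, truth, min_precision = 0.998,
                                   min_bin_sites = 200, depth_cap = 150) {
  tg_all <- align_truth(gm, truth)   # align once for the whole cohort
  res <- lapply(gm$samples, function(s) {
    rng <- tryCatch({
      tab <- depth_concordance(gm, tg_all, s, min_bin_sites, depth_cap)
      select_depth_range(tab, min_precision)
    }, error = function(e) NULL)
    if (is.null(rng))
      data.frame(sample = s, d_lo = NA_integer_, d_hi = NA_integer_,
                 excluded = TRUE)
    else
      data.frame(sample = s, d_lo = rng$d_lo, d_hi = rng$d_hi,
                 excluded = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mask genotype calls outside the calibrated depth range
#'
#' Genotype cells whose depth lies outside the sample's inclusive
#' `[d_lo, d_hi]` range become missing; depths are left unchanged. Depths
#' above the binning cap are compared at their capped value, matching the
#' calibration.
#'
#' @param gm A [genotype_matrix()].
#' @param ranges Data frame from [calibrate_depth_ranges()] (excluded
#'   samples keep all genotypes; they are removed by [run_cascade()]).
#' @param depth_cap Pooling cap used during calibration.
#' @return The masked `genotype_matrix`.
#' @export
apply_depth_filter <- function(gm, ranges, depth_cap = 150) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt <- gm$genotype
  for (k in seq_len(nrow(ranges))) {
    if (isTRUE(ranges$excluded[k])) next
    j <- match(ranges$sample[k], gm$samples)
    if (is.na(j)) next
    dp <- pmin(gm$depth[, j], as.integer(depth_cap))
    out_of_range <- dp < ranges$d_lo[k] | dp > ranges$d_hi[k]
    gt[out_of_range, j] <- NA_integer_
  }
  genotype_matrix(gt, gm$depth, gm$sites, gm$samples)
}

#' Remove sites with excessive missingness
#'
#' Drops sites where the missing-genotype fraction strictly exceeds
#' `max_missing` (default 10%), guaranteeing every surviving site carries
#' at least `ceiling((1 - max_missing) * n_samples)` genotyped samples.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Strict removal threshold.
#' @return Filtered `genotype_matrix`.
#' @export
locus_missingness_filter <- function(gm, max_missing = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  frac <- rowMeans(is.na(gm$genotype))
  subset_matrix(gm, sites = frac <= max_missing)
}

#' Remove sites in repeat classes with poor array concordance
#'
#' Precision is computed per repeat class, pooled over all samples, with the
#' same concordance rule as [depth_concordance()]; sites in classes whose
#' precision is less than or equal to `min_precision` are removed. Classes
#' with no array-truth overlap are retained with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param truth An [array_truth()].
#' @param min_precision Removal threshold (inclusive), default 0.997.
#' @return Filtered `genotype_matrix` with attribute `"class_precision"`.
#' @export
repeat_class_filter <- function(gm, truth, min_precision = 0.997) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tg <- align_truth(gm, truth)
  ngs <- gm$genotype
  is_call <- !is.na(tg) & !is.na(ngs) & ngs >= 1L
  concord <- is_call & ngs == tg
  cls <- gm$sites$repeat_class
  calls_by_class <- tapply(rowSums(is_call), cls, sum)
  conc_by_class <- tapply(rowSums(concord), cls, sum)
  precision <- conc_by_class / calls_by_class
  no_truth <- names(precision)[calls_by_class == 0]
  if (length(no_truth))
    warning("repeat class(es) with no array-truth calls retained: ",
            paste(no_truth, collapse = ", "), call. = FALSE)
  fail <- names(precision)[calls_by_class > 0 & precision <= min_precision]
  out <- subset_matrix(gm, sites = !(cls %in% fail))
  attr(out, "class_precision") <- precision
  out
}

#' Retain only sites confirmed by the second, high-sensitivity caller
#'
#' @param gm A [genotype_matrix()].
#' @param sensitive_sites Character vector of `chrom:pos:ref:alt` keys
#'   discovered by the high-sensitivity calling route.
#' @return Filtered `genotype_matrix`.
#' @export
tool_intersection_filter <- function(gm, sensitive_sites) {
  stopifnot(inherits(gm, "genotype_matrix"))
  subset_matrix(gm, sites = site_keys(gm$sites) %in% sensitive_sites)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts
#' (Levene-Haldane distribution of the heterozygote count): the p-value sums
#' the probabilities of all attainable heterozygote counts no more probable
#' than the observed one. Symmetric in the two homozygote counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts at the site.
#' @return The exact p-value in `(0, 1]`; `NA` for an all-missing site
#'   (zero total), with a warning.
#' @export
#' @examples
#' hwe_exact_test(100, 0, 0)  # monomorphic: p = 1
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) {
    warning("all-missing site: HWE p undefined", call. = FALSE)
    return(NA_real_)
  }
  n_a <- 2 * n_hom_alt + n_het          # minor/major symmetric below
  n1 <- min(n_a, 2 * n - n_a)           # rarer allele count
  if (n1 == 0) return(1.0)
  h_vals <- seq(n1 %% 2, n1, by = 2)    # attainable het counts (parity-bound)
  logw <- h_vals * log(2) -
    lfactorial((n1 - h_vals) / 2) -
    lfactorial(h_vals) -
    lfactorial(n - (n1 + h_vals) / 2)
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h_vals)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Squared Pearson correlation of genotype dosages
#'
#' Concordance metric between sequencing calls and array truth: the squared
#' Pearson correlation of the 0/1/2 dosage codes over cells non-missing on
#' both sides. Undefined (NA) when either side has zero variance or fewer
#' than two overlapping cells.
#'
#' @param calls,truth Integer vectors (or matrices) of genotype codes.
#' @return Single numeric r-squared, or `NA`.
#' @export
genotype_r2 <- function(calls, truth) {
  x <- as.vector(calls)
  y <- as.vector(truth)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Run the full genotype filter cascade
#'
#' Applies, in order: (2) per-sample depth-range calibration and masking,
#' (3) locus missingness, (4) repeat-class precision, (5) caller
#' intersection and (6) exact Hardy-Weinberg filtering. Step numbers follow
#' the convention that step 1 (alignment and raw calling) happens upstream
#' of this package.
#'
#' @param gm Raw `genotype_matrix` (candidate high-confidence calls).
#' @param truth [array_truth()] genotypes for calibration.
#' @param sensitive_sites Site keys discovered by the high-sensitivity
#'   caller (step 5); `NULL` skips the intersection (identity).
#' @param config A [run_config()].
#' @return List with `matrix` (the filtered high-confidence set), `report`
#'   (per-step data frame: `step`, `sites_in`, `sites_out`,
#'   `fraction_removed`), `cells_masked` (step 2 masked-genotype count),
#'   `samples_dropped` (uncalibratable sample ids), `depth_ranges`.
#' @export
run_cascade <- function(gm, truth, sensitive_sites = NULL,
                        config = run_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  steps <- character(0); s_in <- integer(0); s_out <- integer(0)
  note <- function(step, before, after) {
    steps <<- c(steps, step)
    s_in <<- c(s_in, before)
    s_out <<- c(s_out, after)
  }

  if (nrow(gm$genotype) == 0) {
    report <- data.frame(
      step = c("depth", "missingness", "repeat_class", "intersection", "hwe"),
      sites_in = 0L, sites_out = 0L, fraction_removed = 0)
    return(list(matrix = gm, report = report, cells_masked = 0L,
                samples_dropped = character(0), depth_ranges = NULL))
  }

  # step 2: per-sample depth calibration
  ranges <- calibrate_depth_ranges(
    gm, truth,
    min_precision = config$depth_precision_min,
    min_bin_sites = config$min_bin_sites,
    depth_cap = config$depth_cap)
  dropped <- ranges$sample[ranges$excluded]
  if (length(dropped))
    warning("dropping uncalibratable sample(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  kept <- !(gm$samples %in% dropped)
  gm2 <- subset_matrix(gm, samples = kept)
  n_before_mask <- sum(!is.na(gm2$genotype))
  gm2 <- apply_depth_filter(gm2, ranges[!ranges$excluded, , drop = FALSE],
                            depth_cap = config$depth_cap)
  cells_masked <- n_before_mask - sum(!is.na(gm2$genotype))
  note("depth", nrow(gm$genotype), nrow(gm2$genotype))

  # step 3: locus missingness
  gm3 <- locus_missingness_filter(gm2, config$max_missing)
  note("missingness", nrow(gm2$genotype), nrow(gm3$genotype))

  # step 4: repeat-class precision
  gm4 <- repeat_class_filter(gm3, truth, config$repeat_precision_min)
  note("repeat_class", nrow(gm3$genotype), nrow(gm4$genotype))

  # step 5: caller intersection
  gm5 <- if (is.null(sensitive_sites)) gm4 else
    tool_intersection_filter(gm4, sensitive_sites)
  note("intersection", nrow(gm4$genotype), nrow(gm5$genotype))

  # step 6: exact HWE
  keep6 <- hwe_site_filter(gm5, config$hwe_alpha)
  gm6 <- subset_matrix(gm5, sites = keep6)
  note("hwe", nrow(gm5$genotype), nrow(gm6$genotype))

  report <- data.frame(
    step = steps, sites_in = s_in, sites_out = s_out,
    fraction_removed = ifelse(s_in > 0, (s_in - s_out) / s_in, 0))
  list(matrix = gm6, report = report, cells_masked = cells_masked,
       samples_dropped = dropped, depth_ranges = ranges)
}

hwe_site_filter <- function(gm, alpha) {
  gt <- gm$genotype
  n0 <- rowSums(gt == 0L, na.rm = TRUE)
  n1 <- rowSums(gt == 1L, na.rm = TRUE)
  n2 <- rowSums(gt == 2L, na.rm = TRUE)
  p <- vapply(seq_len(nrow(gt)), function(i) {
    if (n0[i] + n1[i] + n2[i] == 0) return(NA_real_)  # retained, warned below
    hwe_exact_test(n0[i], n1[i], n2[i])
  }, 0.0)
  if (anyNA(p))
    warning(sum(is.na(p)), " all-missing site(s) retained (HWE undefined)",
            call. = FALSE)
  is.na(p) | p >= alpha
}

#' Per-individual variant load
#'
#' Counts, per sample, the genotypes at a selected subset of sites (for
#' example: nonsynonymous sites in a given frequency bin, or catalogued
#' disease mutations), split by zygosity.
#'
#' @param gm A [genotype_matrix()].
#' @param sites Logical or integer index selecting the sites to count.
#' @param zygosity `"any"` (het or hom-alt), `"het"`, or `"hom"`.
#' @return List with `counts` (named per-sample vector), `mean` and `sd`
#'   across samples.
#' @export
per_individual_load <- function(gm, sites, zygosity = c("any", "het", "hom")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  zygosity <- match.arg(zygosity)
  gt <- gm$genotype[sites, , drop = FALSE]
  hit <- switch(zygosity,
    any = !is.na(gt) & gt >= 1L,
    het = !is.na(gt) & gt == 1L,
    hom = !is.na(gt) & gt == 2L)
  counts <- colSums(hit)
  names(counts) <- gm$samples
  list(counts = counts, mean = mean(counts), sd = sd(counts))
}
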