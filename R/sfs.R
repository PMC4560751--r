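#' Per-site minor-allele counts and callable sample sizes
#'
#' After the depth filter the number of genotyped individuals varies from
#' site to site, so each segregating site is summarised by its minor-allele
#' copy count `i` and its callable size `n_i` (individuals; `2 * n_i`
#' chromosomes). Monomorphic sites (minor count 0) are dropped.
#'
#' @param gm A filtered [genotype_matrix()].
#' @return Data frame with columns `i` (minor copies), `n_i` (genotyped
#'   individuals), plus the site's `functional_category`, `repeat_class`,
#'   `is_known` and `chromatin_state` carried through for stratification.
#' @export
site_counts <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt <- gm$genotype
  n_i <- rowSums(!is.na(gt))
  alt <- rowSums(gt, na.rm = TRUE)
  minor <- pmin(alt, 2 * n_i - alt)
  keep <- n_i > 0 & minor > 0
  out <- data.frame(
    i = as.integer(minor[keep]),
    n_i = as.integer(n_i[keep]),
    functional_category = gm$sites$functional_category[keep],
    repeat_class = gm$sites$repeat_class[keep],
    is_known = gm$sites$is_known[keep],
    chromatin_state = gm$sites$chromatin_state[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Hypergeometric projection of one site to a smaller sample
#'
#' Probability distribution of the allele count `j` observed when `two_m`
#' chromosomes are drawn without replacement from `two_n` chromosomes
#' carrying `i` copies: `P(j) = C(i,j) C(two_n-i, two_m-j) / C(two_n, two_m)`.
#'
#' @param i Allele copies at the site (`0 <= i <= two_n`).
#' @param two_n Chromosomes genotyped at the site.
#' @param two_m Target chromosome count (`two_m <= two_n`).
#' @return Numeric probability vector over `j = 0..two_m` (sums to 1).
#' @export
#' @examples
#' project_site(1, 4, 2)  # (0.5, 0.5, 0)
project_site <- function(i, two_n, two_m) {
  stopifnot(two_m >= 1, two_m <= two_n, i >= 0, i <= two_n)
  dhyper(0:two_m, i, two_n - i, two_m)
}

#' Folded site frequency spectrum
#'
#' @param counts Numeric vector of (possibly fractional) expected numbers of
#'   segregating sites per minor-allele count `j = 1..m`.
#' @param m Uniform sample size in individuals (`2m` chromosomes).
#' @param category Optional stratum label.
#' @param n_excluded Number of sites excluded because `n_i < m`.
#' @return Object of class `folded_sfs`.
#' @export
folded_sfs <- function(counts, m, category = NA_character_, n_excluded = 0L) {
  counts <- as.numeric(counts)
  if (length(counts) != m)
    stop("a folded SFS at sample size m has m classes (j = 1..m)",
         call. = FALSE)
  if (any(counts < 0)) stop("SFS counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, m = as.integer(m),
                 category = category, n_excluded = as.integer(n_excluded)),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("<folded_sfs> m = %d individuals (%d chromosomes), %.1f sites%s\n",
              x$m, 2 * x$m, sum(x$counts),
              if (is.na(x$category)) "" else paste0(", category ", x$category)))
  invisible(x)
}

#' Project site counts to a uniform sample size
#'
#' Builds the expected folded SFS at `m` individuals by hypergeometric
#' projection of every site: each site contributes its projection
#' probability mass to each minor-allele class, the folded transform is
#' re-applied after projection, and mass projected to monomorphic (`j = 0`)
#' leaks out of the segregating total. Projection is linear, so spectra of
#' site subsets add. Sites with `n_i < m` cannot be projected and are
#' excluded (their number is recorded on the result).
#'
#' @param sites Data frame from [site_counts()] (columns `i`, `n_i`).
#' @param m Target sample size in individuals.
#' @param category Optional stratum label stored on the result.
#' @return A [folded_sfs()] with fractional expected counts.
#' @export
project_sfs <- function(sites, m, category = NA_character_) {
  stopifnot(m >= 1)
  counts <- numeric(m)
  excl <- 0L
  if (nrow(sites) > 0) {
    ok <- sites$n_i >= m
    excl <- sum(!ok)
    grp <- table(sites$i[ok], sites$n_i[ok])
    two_m <- 2L * as.integer(m)
    for (r in seq_len(nrow(grp))) {
      i <- as.integer(rownames(grp)[r])
      for (c in seq_len(ncol(grp))) {
        w <- grp[r, c]
        if (w == 0) next
        two_n <- 2L * as.integer(colnames(grp)[c])
        p <- project_site(i, two_n, two_m)       # j = 0..two_m
        j <- 0:two_m
        jf <- pmin(j, two_m - j)                 # re-fold after projection
        mass <- tapply(p, jf, sum)
        cls <- as.integer(names(mass))
        seg <- cls >= 1L
        counts[cls[seg]] <- counts[cls[seg]] + w * mass[seg]
      }
    }
  }
  folded_sfs(counts, m, category = category, n_excluded = excl)
}

#' Minor-allele-frequency bin of a projected class
#'
#' Bins by `MAF = j / two_m` with inclusive upper bounds:
#' very-rare `<= 0.001` < rare `<= 0.005` < low `<= 0.05` < common.
#'
#' @param j Minor-allele count (>= 1), vectorised.
#' @param two_m Chromosome sample size.
#' @param very_rare,rare,low Bin edges (inclusive upper bounds).
#' @return Factor with levels `very_rare`, `rare`, `low`, `common`.
#' @export
maf_bin <- function(j, two_m, very_rare = 0.001, rare = 0.005, low = 0.05) {
  stopifnot(all(j >= 1))
  maf <- j / two_m
  cut(maf, breaks = c(0, very_rare, rare, low, 0.5),
      labels = c("very_rare", "rare", "low", "common"),
      include.lowest = TRUE, right = TRUE)
}

#' Fraction of very-rare variants (FVRV)
#'
#' The purifying-selection summary of a projected spectrum: the share of
#' its mass at minor allele frequency at or below `very_rare` (0.1% by
#' default). The 95% interval is Clopper-Pearson on the counts rounded
#' half-to-even to integers (projection masses are fractional); the
#' fractional point estimate is reported unrounded.
#'
#' @param sfs A [folded_sfs()].
#' @param very_rare MAF bound of the very-rare bin.
#' @param conf_level Interval coverage, default 0.95.
#' @return List of class `fvrv_result`: `category`, `n_very_rare`,
#'   `n_total`, `fraction`, `ci_low`, `ci_high`.
#' @export
fvrv <- function(sfs, very_rare = 0.001, conf_level = 0.95) {
  stopifnot(inherits(sfs, "folded_sfs"))
  total <- sum(sfs$counts)
  if (total <= 0) stop("empty spectrum: FVRV undefined", call. = FALSE)
  j <- seq_len(sfs$m)
  vr_mass <- sum(sfs$counts[j / (2 * sfs$m) <= very_rare])
  x <- round(vr_mass); n <- round(total)
  x <- min(x, n)
  ci <- if (n >= 1) clopper_pearson(x, n, conf_level) else c(0, 1)
  structure(list(category = sfs$category,
                 n_very_rare = vr_mass, n_total = total,
                 fraction = vr_mass / total,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2])),
            class = "fvrv_result")
}

#' @export
print.fvrv_result <- function(x, ...) {
  cat(sprintf("FVRV%s: %.3f (95%% CI %.3f-%.3f; %.0f of %.0f sites)\n",
              if (is.na(x$category)) "" else paste0(" [", x$category, "]"),
              x$fraction, x$ci_low, x$ci_high, x$n_very_rare, x$n_total))
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param a,b,c,d Cell counts (first row `a`, `b`; second row `c`, `d`).
#' @return Two-sided exact p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d >= 1)
  fisher.test(matrix(c(a, c, b, d), 2, 2))$p.value
}

#' Compare the very-rare fractions of two categories
#'
#' Fisher's exact test on the 2x2 table (very-rare vs not) x (category a vs
#' b), using the projected masses rounded half-to-even to integers.
#'
#' @param a,b [fvrv()] results.
#' @return Two-sided p-value.
#' @export
compare_fractions <- function(a, b) {
  stopifnot(inherits(a, "fvrv_result"), inherits(b, "fvrv_result"))
  fisher_2x2(round(a$n_very_rare), round(a$n_total - a$n_very_rare),
             round(b$n_very_rare), round(b$n_total - b$n_very_rare))
}

#' Uniform projection sample size for a cohort
#'
#' The projection target is the configured fraction of the cohort (90% by
#' default), which by construction of the missingness filter equals the
#' minimum number of genotyped individuals at any surviving site.
#'
#' @param n_samples Cohort size in individuals.
#' @param fraction Projection fraction, default 0.90.
#' @return Integer sample size (individuals).
#' @export
#' @examples
#' projection_size(1070)  # 963
projection_size <- function(n_samples, fraction = 0.90) {
  as.integer(floor(fraction * n_samples))
}
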