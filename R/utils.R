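#' Clopper-Pearson binomial confidence interval
#'
#' Exact (conservative) two-sided interval for a binomial proportion, the
#' interval used for both the fraction-of-very-rare-variants statistic and
#' validation FDR estimates.
#'
#' @param x Number of successes (non-negative integer).
#' @param n Number of trials (positive integer, `x <= n`).
#' @param conf_level Coverage level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(0, 174)
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# nearest even integer; exact odd integers resolve downward
round_even_tie_down <- function(x) {
  lo <- 2 * floor(x / 2)
  hi <- lo + 2
  ifelse(hi - x < x - lo, hi, lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

site_keys <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}
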