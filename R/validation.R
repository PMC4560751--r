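#' Resolve a site's multi-platform validation status
#'
#' Deterministic resolution of one validation record into `true`, `false`
#' or `nocall`:
#'
#' * if either mass-spectrometry genotyping or amplicon sequencing yields a
#'   no-call, the site is a no-call — unless Sanger sequencing rescues it,
#'   in which case Sanger's verdict (assumed truth) decides;
#' * platforms that both report agree: that verdict stands (both-true is a
#'   validated true positive);
#' * platforms disagree: Sanger arbitrates; without Sanger the site is a
#'   no-call;
#' * a single reporting platform decides alone; Sanger alone decides alone.
#'
#' @param massarray One of `"true"`, `"false"`, `"nocall"`, `"absent"`.
#' @param amplicon Same domain as `massarray`.
#' @param sanger One of `"true"`, `"false"`, `"absent"`.
#' @return `"true"`, `"false"` or `"nocall"`.
#' @export
resolve_status <- function(massarray, amplicon, sanger = "absent") {
  massarray <- match.arg(massarray, c("true", "false", "nocall", "absent"))
  amplicon <- match.arg(amplicon, c("true", "false", "nocall", "absent"))
  sanger <- match.arg(sanger, c("true", "false", "absent"))
  if (massarray == "nocall" || amplicon == "nocall")
    return(if (sanger != "absent") sanger else "nocall")
  verdicts <- c(massarray, amplicon)
  verdicts <- verdicts[verdicts != "absent"]
  if (length(verdicts) == 0)
    return(if (sanger != "absent") sanger else "nocall")
  if (length(unique(verdicts)) == 1) return(verdicts[1])
  if (sanger != "absent") sanger else "nocall"
}

#' Validation-based FDR estimate
#'
#' Resolves each record with [resolve_status()] and estimates the false
#' discovery rate as `false / (true + false)`; no-calls are excluded from
#' the denominator. The 95% interval is Clopper-Pearson.
#'
#' @param records Data frame with columns `massarray`, `amplicon`,
#'   `sanger` (platform outcomes as in [resolve_status()]); an optional
#'   `known` column is ignored here.
#' @param conf_level Interval coverage, default 0.95.
#' @return List of class `fdr_estimate`: `n_true`, `n_false`, `n_nocall`,
#'   `fdr`, `ci_low`, `ci_high`.
#' @export
fdr_estimate <- function(records, conf_level = 0.95) {
  status <- mapply(resolve_status, records$massarray, records$amplicon,
                   records$sanger %||% rep("absent", nrow(records)))
  n_true <- sum(status == "true")
  n_false <- sum(status == "false")
  n_nocall <- sum(status == "nocall")
  if (n_true + n_false < 1)
    stop("no resolved validation outcomes: FDR undefined", call. = FALSE)
  ci <- clopper_pearson(n_false, n_true + n_false, conf_level)
  structure(list(n_true = n_true, n_false = n_false, n_nocall = n_nocall,
                 fdr = n_false / (n_true + n_false),
                 ci_low = unname(ci[1]), ci_high = unname(ci[2])),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("FDR %.2f%% (%d of %d; 95%% CI %.2f-%.2f%%; %d no-calls)\n",
              100 * x$fdr, x$n_false, x$n_true + x$n_false,
              100 * x$ci_low, 100 * x$ci_high, x$n_nocall))
  invisible(x)
}

#' Combined known/novel FDR
#'
#' Overall per-site FDR as the mixture
#' `fdr_known * f_known + fdr_novel * (1 - f_known)`, with the convention
#' that catalogued (known) variants carry FDR 0 unless measured otherwise.
#'
#' @param fdr_known FDR among known variants, in `[0, 1]`.
#' @param fdr_novel FDR among novel variants, in `[0, 1]`.
#' @param f_known Fraction of variants that are known, in `[0, 1]`.
#' @return Overall FDR.
#' @export
#' @examples
#' combined_fdr(0, 0.02, 0.6)  # 0.008
combined_fdr <- function(fdr_known, fdr_novel, f_known) {
  assert_fraction(fdr_known, "fdr_known")
  assert_fraction(fdr_novel, "fdr_novel")
  assert_fraction(f_known, "f_known")
  fdr_known * f_known + fdr_novel * (1 - f_known)
}

#' Novelty rate
#'
#' Fraction of called variants absent from the reference variant catalogue,
#' as a percentage rounded to two decimals.
#'
#' @param n_known,n_novel Variant counts.
#' @return Novelty rate in percent.
#' @export
#' @examples
#' novelty_rate(9219783, 12001412)  # 56.55
novelty_rate <- function(n_known, n_novel) {
  stopifnot(n_known >= 0, n_novel >= 0)
  if (n_known + n_novel < 1)
    stop("novelty rate undefined for zero variants", call. = FALSE)
  round(100 * n_novel / (n_known + n_novel), 2)
}

#' Read a validation-panel table
#'
#' Tab-separated with header `site massarray amplicon sanger known`.
#'
#' @param path File path.
#' @return Data frame of validation records.
#' @export
read_validation_panel <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("site", "massarray", "amplicon", "sanger", "known")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("validation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$known <- as.logical(tab$known)
  tab
}
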