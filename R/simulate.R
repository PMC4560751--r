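#' Simulation configuration for the synthetic cohort
#'
#' Collects every knob of the cohort generator. The defaults emulate the
#' study conditions of a deep whole-genome population panel: 1,070
#' individuals at 32.4x mean autosomal coverage, negative-binomially
#' dispersed per-cell depths, site frequencies drawn from the folded
#' expected spectrum of a recent-expansion demographic model, genotype
#' errors concentrated at extreme depths and in unstable repeat classes,
#' a small fraction of sites with planted excess heterozygosity (reference
#' artefact surrogate), SNP-array truth at a common-variant subset, a
#' high-sensitivity caller superset with decoy sites, and an amylase locus
#' whose copy-unit count follows the diplotype model `y = 2n + 2`.
#'
#' @param model Demographic model frequencies are drawn from.
#' @param n_samples Cohort size (individuals).
#' @param n_sites Number of variant sites.
#' @param two_n_pop Resolution (chromosomes) of the population frequency
#'   grid the spectrum is discretised on.
#' @param mean_depth Cohort mean coverage; per-sample means vary around it.
#' @param depth_sample_sd Standard deviation of per-sample mean depths.
#' @param nb_size Negative-binomial size (dispersion) of per-cell depth.
#' @param eps0 Baseline per-genotype error probability.
#' @param depth_lo,mult_lo Depth below which errors are `mult_lo`-fold.
#' @param depth_hi,mult_hi Depth above which errors are `mult_hi`-fold.
#' @param repeat_mult Named per-repeat-class error multipliers (classes not
#'   named multiply by 1).
#' @param hwe_artifact_fraction Fraction of sites with planted
#'   excess-heterozygosity artefacts.
#' @param hwe_delta Additive heterozygote-probability inflation at
#'   artefact sites (`P(het) = min(1, 2pq + delta)`).
#' @param category_props Named functional-category proportions.
#' @param category_shift Named per-category rare-shift parameters
#'   (geometric tilt of the spectrum toward singletons; 0 = neutral).
#' @param repeat_props Named repeat-class proportions.
#' @param array_fraction Fraction of eligible (common) sites with SNP-array
#'   truth genotypes.
#' @param array_maf_min Minimum population MAF for array eligibility
#'   (arrays are designed on common variants).
#' @param array_repeat_attenuation Relative array coverage of sites in
#'   repeat classes with elevated error (array probes largely avoid
#'   repetitive sequence).
#' @param decoy_rate Decoy sites in the high-sensitivity superset, as a
#'   fraction of true sites.
#' @param known_prob_common,known_prob_rare Probability a common / rare
#'   site is in the reference variant catalogue.
#' @param unit_mean Mean of the Poisson-distributed amylase copy-unit
#'   count `n` (the default gives mean summed AMY1 copies
#'   `2 * 3.135 + 2 = 8.27`).
#' @param val_fdr Planted false fraction in the validation panel.
#' @param val_nocall_rate,val_error_rate Per-platform no-call and verdict
#'   error rates.
#' @param val_sanger_rate Probability Sanger sequencing is available for a
#'   record.
#' @param seed Non-negative integer seed; identical seeds reproduce
#'   identical outputs.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(model = default_demographic_model(),
                       n_samples = 1070,
                       n_sites = 10000,
                       two_n_pop = 2000,
                       mean_depth = 32.4,
                       depth_sample_sd = 2.0,
                       nb_size = 10,
                       eps0 = 1e-4,
                       depth_lo = 8, mult_lo = 100,
                       depth_hi = 120, mult_hi = 20,
                       repeat_mult = c(Simple_repeat = 30,
                                       Low_complexity = 20,
                                       Satellite = 30),
                       hwe_artifact_fraction = 0.01,
                       hwe_delta = 0.9,
                       category_props = c(intergenic = 0.55, intron = 0.30,
                                          lincrna = 0.05, utr3 = 0.02,
                                          synonymous = 0.012,
                                          nonsynonymous = 0.012,
                                          utr5 = 0.005, mirna = 0.001,
                                          stop_gained = 0.0005,
                                          other = 0.0495),
                       category_shift = c(intergenic = 0, intron = 0.001,
                                          lincrna = 0.002, utr3 = 0.0025,
                                          synonymous = 0.002,
                                          nonsynonymous = 0.006,
                                          utr5 = 0.003, mirna = 0.006,
                                          stop_gained = 0.02, other = 0.001),
                       repeat_props = c(none = 0.70, Alu = 0.10,
                                        Simple_repeat = 0.05,
                                        Low_complexity = 0.05,
                                        ERVK = 0.02, Satellite = 0.02,
                                        `TcMar-Mariner` = 0.02,
                                        other = 0.04),
                       array_fraction = 0.30,
                       array_maf_min = 0.05,
                       array_repeat_attenuation = 0.20,
                       decoy_rate = 0.02,
                       known_prob_common = 0.95,
                       known_prob_rare = 0.40,
                       unit_mean = 3.135,
                       val_fdr = 0.05,
                       val_nocall_rate = 0.10,
                       val_error_rate = 0.0,
                       val_sanger_rate = 1.0,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(inherits(model, "demographic_model"))
  if (n_samples < 1 || n_sites < 0) stop("invalid cohort size", call. = FALSE)
  if (two_n_pop < 4) stop("two_n_pop too small", call. = FALSE)
  for (nm in c("eps0", "hwe_artifact_fraction", "hwe_delta",
               "array_fraction", "array_maf_min", "array_repeat_attenuation",
               "decoy_rate",
               "known_prob_common", "known_prob_rare", "val_fdr",
               "val_nocall_rate", "val_error_rate", "val_sanger_rate"))
    assert_fraction(cfg[[nm]], nm)
  if (abs(sum(category_props) - 1) > 1e-6)
    stop("category_props must sum to 1", call. = FALSE)
  if (abs(sum(repeat_props) - 1) > 1e-6)
    stop("repeat_props must sum to 1", call. = FALSE)
  if (!all(names(category_shift) %in% FUNCTIONAL_CATEGORIES) ||
      !all(names(category_props) %in% FUNCTIONAL_CATEGORIES))
    stop("unknown functional category in configuration", call. = FALSE)
  if (any(category_shift < 0))
    stop("rare-shift parameters must be >= 0", call. = FALSE)
  if (cfg$seed < 0) stop("seed must be non-negative", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Simulate a cohort genotype matrix with calibration truth
#'
#' Generates the full input bundle of the filtering pipeline from a
#' [sim_config()]: site population frequencies are drawn proportional to
#' the (per-category rare-shifted) folded expected spectrum of the
#' configured demographic model; genotypes follow Hardy-Weinberg at the
#' drawn frequency (except planted excess-heterozygote artefact sites);
#' per-cell depths are negative-binomial around per-sample means; genotype
#' errors replace the true code with a uniformly chosen different code at
#' a rate set by depth and repeat class; SNP-array truth holds error-free
#' genotypes at a common-variant subset; the high-sensitivity superset
#' contains every true site plus decoys. Cells with zero depth are
#' reported missing.
#'
#' @param config A [sim_config()].
#' @return List with elements `matrix` (a [genotype_matrix()]), `truth`
#'   (an [array_truth()]), `sensitive_sites` (character site keys), and
#'   `sim_truth` (list: `freq`, `true_genotype`, `error_cells`,
#'   `artifact_sites`, `array_site_index`, `config`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  np <- config$n_samples
  grid <- config$two_n_pop

  phi <- expected_sfs(config$model, grid, folded = TRUE)  # classes 1..grid/2

  # per-site category, repeat class, frequency (rare-shift tilts the SFS)
  category <- sample(names(config$category_props), ns, replace = TRUE,
                     prob = config$category_props)
  repeat_class <- sample(names(config$repeat_props), ns, replace = TRUE,
                         prob = config$repeat_props)
  j_class <- integer(ns)
  jj <- seq_along(phi)
  for (cat in unique(category)) {
    sel <- category == cat
    sigma <- config$category_shift[[cat]] %||% 0
    w <- phi * exp(-sigma * (jj - 1))
    j_class[sel] <- sample(jj, sum(sel), replace = TRUE, prob = w)
  }
  freq <- j_class / grid

  pos <- sort(sample.int(2.5e8, ns))
  sites <- data.frame(
    chrom = "chr1", pos = pos,
    ref = sample(c("A", "C", "G", "T"), ns, replace = TRUE),
    alt = NA_character_, stringsAsFactors = FALSE)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  common <- freq >= 0.05
  sites$is_known <- runif(ns) < ifelse(common, config$known_prob_common,
                                       config$known_prob_rare)
  sites$functional_category <- category
  sites$repeat_class <- repeat_class
  sites$chromatin_state <- NA_character_

  # genotype probabilities under HWE, with planted excess-het artefacts
  artifact <- runif(ns) < config$hwe_artifact_fraction
  p <- freq; q <- 1 - p
  p_het <- 2 * p * q
  p_het[artifact] <- pmin(1, p_het[artifact] + config$hwe_delta)
  rest <- 1 - p_het
  denom <- q^2 + p^2
  p_hom_ref <- rest * q^2 / denom
  u <- matrix(runif(ns * np), ns, np)
  gt_true <- (u > p_hom_ref) + (u > p_hom_ref + p_het)
  storage.mode(gt_true) <- "integer"

  # depths: negative binomial around per-sample means
  mu_s <- pmax(5, stats::rnorm(np, config$mean_depth, config$depth_sample_sd))
  depth <- matrix(0L, ns, np)
  for (j in seq_len(np))
    depth[, j] <- rnbinom(ns, size = config$nb_size, mu = mu_s[j])

  # depth- and repeat-dependent genotype errors
  mult_rep <- rep(1, ns)
  for (cls in names(config$repeat_mult))
    mult_rep[repeat_class == cls] <- config$repeat_mult[[cls]]
  p_err <- matrix(config$eps0 * mult_rep, ns, np)
  p_err[depth < config$depth_lo] <- p_err[depth < config$depth_lo] *
    config$mult_lo
  p_err[depth > config$depth_hi] <- p_err[depth > config$depth_hi] *
    config$mult_hi
  p_err <- pmin(p_err, 0.5)
  err <- matrix(runif(ns * np), ns, np) < p_err
  shift <- matrix(sample(c(1L, 2L), ns * np, replace = TRUE), ns, np)
  gt_obs <- gt_true
  gt_obs[err] <- (gt_true[err] + shift[err]) %% 3L
  gt_obs[depth == 0L] <- NA_integer_

  gm <- genotype_matrix(gt_obs, depth, sites, sprintf("S%04d", seq_len(np)))

  # SNP-array truth: error-free genotypes at a common-variant subset;
  # probe design under-covers repeat classes with elevated error
  eligible <- which(freq >= config$array_maf_min)
  incl <- config$array_fraction *
    ifelse(mult_rep[eligible] > 1, config$array_repeat_attenuation, 1)
  truth_idx <- eligible[runif(length(eligible)) < incl]
  tg <- matrix(NA_integer_, ns, np, dimnames = dimnames(gm$genotype))
  tg[truth_idx, ] <- gt_true[truth_idx, ]
  truth <- array_truth(tg, gm$samples)

  # high-sensitivity superset: all true sites plus decoys
  keys <- site_keys(sites)
  n_decoy <- round(config$decoy_rate * ns)
  decoy_pos <- sample.int(2.5e8, n_decoy)
  decoys <- paste("chr1", decoy_pos, "A", "G", sep = ":")
  sensitive <- unique(c(keys, decoys))

  list(
    matrix = gm, truth = truth, sensitive_sites = sensitive,
    sim_truth = list(freq = freq, true_genotype = gt_true,
                     error_cells = err, artifact_sites = artifact,
                     array_site_index = truth_idx, config = config)
  )
}

#' Simulate amylase-locus depth tracks with planted copy units
#'
#' Each sample carries a Poisson-distributed diploid count `n` of the
#' amylase copy unit; summed AMY1 gene copies are `y = 2n + 2` (`n` copies
#' each of AMY1A and AMY1B plus the two fixed AMY1C copies), Region X
#' carries `n` copies, and control/reference regions (AMY2B, Region Y,
#' Region Z) are diploid. Expected mean region depth is
#' `base_depth * copies / 2`; with `noise = "poisson"` the observed mean is
#' a Poisson total over the region length divided by that length.
#'
#' @param n_samples Number of samples.
#' @param base_depth Diploid coverage of the sample.
#' @param unit_mean Poisson mean of the unit count `n`.
#' @param noise `"poisson"` or `"none"` (exact expectations).
#' @param seed Seed.
#' @return List with `profile` (a [region_depth_profile()]) and `truth`
#'   (data frame `sample`, `n_units`, `y`).
#' @export
simulate_amylase_tracks <- function(n_samples = 1070, base_depth = 32.4,
                                    unit_mean = 3.135,
                                    noise = c("poisson", "none"),
                                    seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  regions <- amylase_regions()
  len <- setNames(regions$end - regions$start + 1, regions$region)
  n_units <- rpois(n_samples, unit_mean)
  copies <- cbind(
    AMY2B = rep(2, n_samples), AMY1A = n_units, AMY1B = n_units,
    AMY1C = rep(2, n_samples), RegionX = n_units,
    RegionY = rep(2, n_samples), RegionZ = rep(2, n_samples))
  expected <- base_depth * copies / 2
  obs <- expected
  if (noise == "poisson") {
    for (r in colnames(expected))
      obs[, r] <- rpois(n_samples, expected[, r] * len[[r]]) / len[[r]]
  }
  rownames(obs) <- sprintf("S%04d", seq_len(n_samples))
  list(profile = region_depth_profile(obs),
       truth = data.frame(sample = rownames(obs), n_units = n_units,
                          y = 2 * n_units + 2, stringsAsFactors = FALSE))
}

#' Simulate a multi-platform validation panel
#'
#' Plants true/false statuses at the configured false rate and generates
#' platform outcomes under per-platform no-call and verdict-error rates;
#' Sanger sequencing, when available for a record, always reports the
#' planted truth.
#'
#' @param n_records Panel size.
#' @param fdr Planted false fraction.
#' @param nocall_rate Per-platform no-call probability.
#' @param error_rate Per-platform verdict-flip probability.
#' @param sanger_rate Probability Sanger data exist for a record.
#' @param known_fraction Fraction of records flagged as catalogued.
#' @param seed Seed.
#' @return List with `records` (data frame `site`, `massarray`,
#'   `amplicon`, `sanger`, `known`) and `truth` (planted status vector).
#' @export
simulate_validation_panel <- function(n_records = 322, fdr = 0.05,
                                      nocall_rate = 0.10, error_rate = 0.0,
                                      sanger_rate = 1.0,
                                      known_fraction = 0.5, seed = 1L) {
  for (nm in c("fdr", "nocall_rate", "error_rate", "sanger_rate",
               "known_fraction"))
    assert_fraction(get(nm), nm)
  set.seed(seed)
  planted <- ifelse(runif(n_records) < fdr, "false", "true")
  platform <- function() {
    verdict <- planted
    flip <- runif(n_records) < error_rate
    verdict[flip] <- ifelse(planted[flip] == "true", "false", "true")
    verdict[runif(n_records) < nocall_rate] <- "nocall"
    verdict
  }
  sanger <- ifelse(runif(n_records) < sanger_rate, planted, "absent")
  records <- data.frame(
    site = sprintf("chr1:%d:A:G", seq_len(n_records)),
    massarray = platform(), amplicon = platform(), sanger = sanger,
    known = runif(n_records) < known_fraction,
    stringsAsFactors = FALSE)
  list(records = records, truth = planted)
}
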