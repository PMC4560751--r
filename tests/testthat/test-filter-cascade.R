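test_that("depth concordance computes precision and recall per depth bin", {
  # 100 concordant het calls at depth 30
  fx <- controlled_truth_pair(100, rep(30L, 100), rep(1L, 100), rep(1L, 100))
  tab <- depth_concordance(fx$gm, fx$truth, "S1", min_bin_sites = 10)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$precision, 1.0)
  expect_equal(tab$recall, 1.0)

  # 997 concordant of 1000 calls in one bin
  ngs <- rep(1L, 1000); truth <- rep(1L, 1000); truth[1:3] <- 2L
  fx <- controlled_truth_pair(1000, rep(25L, 1000), ngs, truth)
  tab <- depth_concordance(fx$gm, fx$truth, "S1", min_bin_sites = 10)
  expect_equal(tab$precision, 0.997)

  # no overlapping truth
  fx <- controlled_truth_pair(5, rep(30L, 5), rep(1L, 5), rep(NA_integer_, 5))
  expect_error(depth_concordance(fx$gm, fx$truth, "S1"), "no overlapping")
})

test_that("planted low-depth errors are localised to the failing bins", {
  # low-coverage cohort: error rate 1% below depth 8, 1e-5 at higher depths
  cfg <- sim_config(model = demographic_model(1e4), two_n_pop = 200,
                    n_samples = 3, n_sites = 30000, mean_depth = 12,
                    depth_sample_sd = 0, nb_size = 3, eps0 = 2e-5,
                    depth_lo = 8, mult_lo = 500, depth_hi = 1000,
                    array_fraction = 1, array_maf_min = 0.1,
                    array_repeat_attenuation = 1,
                    hwe_artifact_fraction = 0, seed = 99)
  sim <- simulate_cohort(cfg)
  tab <- depth_concordance(sim$matrix, sim$truth, "S0002",
                           min_bin_sites = 100)
  low <- tab[tab$depth_hi < 8, ]
  high <- tab[tab$depth_lo >= 8, ]
  expect_true(nrow(low) >= 3 && nrow(high) >= 5)
  expect_true(all(low$precision < 0.998))
  expect_true(all(high$precision > 0.998))
  # the selected retention range starts exactly at the planted cutoff
  rng <- select_depth_range(tab)
  expect_equal(rng$d_lo, 8)

  # precision equals direct counting of planted errors in each bin
  j <- match("S0002", sim$matrix$samples)
  tg <- sim$truth$genotype[, j]
  ngs <- sim$matrix$genotype[, j]
  dp <- pmin(sim$matrix$depth[, j], 150L)
  for (r in seq_len(nrow(tab))) {
    cells <- !is.na(tg) & !is.na(ngs) & ngs >= 1L &
      dp >= tab$depth_lo[r] & dp <= tab$depth_hi[r]
    expect_equal(tab$precision[r], mean(ngs[cells] == tg[cells]))
  }
})

test_that("depth range selection takes the longest passing run", {
  tab <- data.frame(depth_lo = 10:19, depth_hi = 10:19,
                    n_calls = rep(1000L, 10), precision = rep(0.999, 10))
  tab$precision[c(3, 4)] <- 0.99   # runs: 10-11 (len 2), 14-19 (len 6)
  rng <- select_depth_range(tab)
  expect_equal(rng, list(d_lo = 14, d_hi = 19))

  # all pass: full observed span
  tab$precision <- 0.9995
  expect_equal(select_depth_range(tab), list(d_lo = 10, d_hi = 19))

  # equal-length runs tie toward more calls
  tab$precision <- c(0.999, 0.999, 0.99, 0.999, 0.999, 0.99, 0.999, 0.999,
                     0.99, 0.99)
  tab$n_calls <- c(100L, 100L, 0L, 900L, 900L, 0L, 200L, 200L, 0L, 0L)
  tab$n_calls[tab$n_calls == 0L] <- 1000L
  rng <- select_depth_range(tab)
  expect_equal(rng$d_lo, 13)

  # exact threshold is not a pass (strict >)
  tab2 <- data.frame(depth_lo = 1, depth_hi = 1, n_calls = 1000L,
                     precision = 0.998)
  expect_error(select_depth_range(tab2), "uncalibratable")
})

test_that("depth filter masks genotypes outside the inclusive range", {
  gm <- toy_matrix()
  ranges <- data.frame(sample = c("S1", "S2", "S3"), d_lo = c(12L, 20L, 22L),
                       d_hi = c(80L, 30L, 40L), excluded = FALSE)
  out <- apply_depth_filter(gm, ranges)
  expect_true(is.na(out$genotype[2, 1]))     # depth 10 < 12 masked
  expect_identical(unname(out$genotype[1, 1]), 0L)  # depth 30 kept
  expect_identical(out$depth, gm$depth)      # depths unchanged

  # boundary depths are retained
  fx <- controlled_truth_pair(3, c(12L, 11L, 80L), c(1L, 1L, 1L), rep(1L, 3))
  r1 <- data.frame(sample = "S1", d_lo = 12L, d_hi = 80L, excluded = FALSE)
  msk <- apply_depth_filter(fx$gm, r1)
  expect_identical(unname(msk$genotype[, 1]), c(1L, NA, 1L))

  # masked count equals the brute-force count on a seeded cohort
  sim <- simulate_cohort(sim_config(n_samples = 6, n_sites = 500, seed = 5))
  rg <- data.frame(sample = sim$matrix$samples, d_lo = 20L, d_hi = 45L,
                   excluded = FALSE)
  out <- apply_depth_filter(sim$matrix, rg)
  direct <- sum(!is.na(sim$matrix$genotype) &
                (sim$matrix$depth < 20 | pmin(sim$matrix$depth, 150) > 45))
  expect_equal(sum(!is.na(sim$matrix$genotype)) - sum(!is.na(out$genotype)),
               direct)
})

test_that("missingness filter removes sites strictly above the threshold", {
  # 1,070 samples: 107 missing (10.0%) retained, 108 removed
  n <- 1070
  gt <- matrix(1L, nrow = 2, ncol = n)
  gt[1, seq_len(107)] <- NA
  gt[2, seq_len(108)] <- NA
  sites <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G")
  gm <- genotype_matrix(gt, matrix(30L, 2, n), sites, sprintf("S%04d", 1:n))
  out <- locus_missingness_filter(gm, 0.10)
  expect_equal(nrow(out$genotype), 1)
  expect_equal(out$sites$pos, 1L)
  # surviving site has >= ceil(0.9 n) genotyped samples
  expect_gte(sum(!is.na(out$genotype[1, ])), ceiling(0.9 * n))

  # no missing cells: unchanged; 2 of 10 missing: removed
  gm2 <- toy_matrix()
  expect_equal(nrow(locus_missingness_filter(gm2)$genotype), 2)
  gt3 <- matrix(1L, 1, 10); gt3[1, 1:2] <- NA
  gm3 <- genotype_matrix(gt3, matrix(30L, 1, 10),
                         data.frame(chrom = "chr1", pos = 1, ref = "A",
                                    alt = "G"), paste0("S", 1:10))
  expect_equal(nrow(locus_missingness_filter(gm3)$genotype), 0)
})

test_that("repeat-class filter removes classes at or below the precision bound", {
  # craft: class 'Alu' precision exactly 0.997 (removed), 'none' 0.998 (kept)
  n_a <- 1000; n_n <- 1000
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_a + n_n), ref = "A",
                      alt = "G",
                      repeat_class = rep(c("Alu", "none"), c(n_a, n_n)),
                      stringsAsFactors = FALSE)
  ngs <- rep(1L, n_a + n_n)
  truth <- rep(1L, n_a + n_n)
  truth[1:3] <- 0L          # 997/1000 in Alu
  truth[n_a + (1:2)] <- 0L  # 998/1000 in none
  gm <- genotype_matrix(matrix(ngs, ncol = 1), matrix(30L, n_a + n_n, 1),
                        sites, "S1")
  tr <- array_truth(matrix(truth, ncol = 1), "S1")
  rownames(tr$genotype) <- rownames(gm$genotype)
  out <- repeat_class_filter(gm, tr, 0.997)
  expect_identical(unique(out$sites$repeat_class), "none")
  expect_equal(nrow(out$genotype), n_n)

  # classes with no truth overlap are retained with a warning
  sites$repeat_class[1:10] <- "ERVK"
  truth[1:10] <- NA
  gm <- genotype_matrix(matrix(ngs, ncol = 1), matrix(30L, n_a + n_n, 1),
                        sites, "S1")
  tr <- array_truth(matrix(truth, ncol = 1), "S1")
  rownames(tr$genotype) <- rownames(gm$genotype)
  expect_warning(out2 <- repeat_class_filter(gm, tr, 0.997), "ERVK")
  expect_true("ERVK" %in% out2$sites$repeat_class)
})

test_that("a planted high-error repeat class is removed, and only it", {
  cfg <- sim_config(n_samples = 40, n_sites = 4000, eps0 = 1e-4,
                    repeat_mult = c(Simple_repeat = 500),
                    repeat_props = c(none = 0.8, Simple_repeat = 0.2),
                    array_fraction = 1, array_maf_min = 0.05,
                    array_repeat_attenuation = 1,
                    hwe_artifact_fraction = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  out <- repeat_class_filter(sim$matrix, sim$truth, 0.997)
  planted <- sim$matrix$sites$repeat_class == "Simple_repeat"
  expect_identical(rownames(out$genotype),
                   rownames(sim$matrix$genotype)[!planted])
})

test_that("caller-intersection filter is exact set arithmetic", {
  gm <- toy_matrix()
  keys <- paste(gm$sites$chrom, gm$sites$pos, gm$sites$ref, gm$sites$alt,
                sep = ":")
  expect_identical(tool_intersection_filter(gm, keys)$sites, gm$sites)
  expect_equal(nrow(tool_intersection_filter(gm, character(0))$genotype), 0)
  out <- tool_intersection_filter(gm, keys[c(1, 3)])
  expect_equal(nrow(out$genotype), 2)
})

test_that("exact HWE test matches its enumeration oracle and symmetries", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_equal(hwe_exact_test(12, 7, 4), hwe_exact_test(4, 7, 12))
  expect_warning(p <- hwe_exact_test(0, 0, 0), "undefined")
  expect_true(is.na(p))
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(1:25, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    p1 <- hwe_exact_test(a, b, c)
    expect_equal(p1, hwe_oracle(a, b, c), tolerance = 1e-12)
    expect_gt(p1, 0); expect_lte(p1, 1)
  }
})

test_that("genotype r-squared equals the squared Pearson correlation", {
  expect_equal(genotype_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1.0)
  expect_equal(genotype_r2(c(0, 1, 2, 1), 2 - c(0, 1, 2, 1)), 1.0)
  expect_true(is.na(genotype_r2(c(1, 1, 1), c(0, 1, 2))))  # zero variance
  set.seed(4)
  x <- sample(0:2, 200, replace = TRUE)
  y <- ifelse(runif(200) < 0.1, sample(0:2, 200, replace = TRUE), x)
  mx <- mean(x); my <- mean(y)
  direct <- (sum((x - mx) * (y - my)))^2 /
    (sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(genotype_r2(x, y), direct)
})

test_that("cascade handles empty input and is the identity on clean cohorts", {
  sites0 <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0))
  empty <- genotype_matrix(matrix(integer(0), 0, 2),
                           matrix(integer(0), 0, 2), sites0, c("A", "B"))
  res <- run_cascade(empty, array_truth(matrix(integer(0), 0, 2), c("A", "B")))
  expect_equal(nrow(res$matrix$genotype), 0)
  expect_true(all(res$report$fraction_removed == 0))

  # truth at every site so the calibrated depth span covers all cells
  cfg <- sim_config(n_samples = 30, n_sites = 800, eps0 = 0,
                    hwe_artifact_fraction = 0, array_fraction = 1,
                    array_maf_min = 0, array_repeat_attenuation = 1,
                    seed = 2)
  sim <- simulate_cohort(cfg)
  res <- suppressWarnings(run_cascade(sim$matrix, sim$truth,
                                      sensitive_sites = NULL))
  expect_identical(res$matrix$genotype, sim$matrix$genotype)
  expect_equal(res$report$fraction_removed,
               (res$report$sites_in - res$report$sites_out) /
                 res$report$sites_in)
})

test_that("cascade filters are idempotent and never add sites", {
  sim <- simulate_cohort(sim_config(n_samples = 40, n_sites = 1500, seed = 8))
  res <- suppressWarnings(run_cascade(sim$matrix, sim$truth,
                                      sim$sensitive_sites))
  expect_true(all(res$report$sites_out <= res$report$sites_in))

  m1 <- locus_missingness_filter(sim$matrix)
  expect_identical(locus_missingness_filter(m1)$genotype, m1$genotype)
  h1 <- subset_matrix(sim$matrix,
                      sites = panelforge:::hwe_site_filter(sim$matrix, 1e-5))
  h2 <- subset_matrix(h1, sites = panelforge:::hwe_site_filter(h1, 1e-5))
  expect_identical(h2$genotype, h1$genotype)
})

test_that("per-individual load counts genotypes at selected sites", {
  gm <- toy_matrix()
  load_all <- per_individual_load(gm, rep(TRUE, 3))
  expect_equal(unname(load_all$counts), c(2, 2, 2))
  # single site, all het
  gt <- matrix(1L, 1, 4)
  gm1 <- genotype_matrix(gt, matrix(30L, 1, 4),
                         data.frame(chrom = "chr1", pos = 1, ref = "A",
                                    alt = "G"), paste0("S", 1:4))
  l <- per_individual_load(gm1, 1)
  expect_equal(l$mean, 1.0); expect_equal(l$sd, 0.0)
  # empty predicate
  l0 <- per_individual_load(gm, rep(FALSE, 3))
  expect_equal(unname(l0$counts), c(0, 0, 0))
  # zygosity split matches direct tabulation on a seeded cohort
  sim <- simulate_cohort(sim_config(n_samples = 12, n_sites = 300, seed = 6))
  sel <- sim$matrix$sites$functional_category == "intron"
  l2 <- per_individual_load(sim$matrix, sel, "hom")
  direct <- colSums(sim$matrix$genotype[sel, , drop = FALSE] == 2L,
                    na.rm = TRUE)
  expect_equal(unname(l2$counts), unname(direct))
})
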