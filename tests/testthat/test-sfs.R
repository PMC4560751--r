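test_that("site counts fold to the minor allele and drop monomorphic sites", {
  gt <- rbind(c(0L, 1L, 2L),   # alt copies 3 of 6 -> minor 3
              c(0L, 0L, 0L),   # monomorphic: dropped
              c(2L, 2L, 2L),   # monomorphic for alt: dropped (folded)
              c(2L, NA, 0L))   # alt 2 of 4 -> minor 2, n_i = 2
  sites <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G")
  gm <- genotype_matrix(gt, matrix(30L, 4, 3), sites, c("a", "b", "c"))
  sc <- site_counts(gm)
  expect_equal(sc$i, c(3L, 2L))
  expect_equal(sc$n_i, c(3L, 2L))

  sim <- simulate_cohort(sim_config(n_samples = 15, n_sites = 400, seed = 12))
  sc2 <- site_counts(sim$matrix)
  alt <- rowSums(sim$matrix$genotype, na.rm = TRUE)
  ni <- rowSums(!is.na(sim$matrix$genotype))
  minor <- pmin(alt, 2 * ni - alt)
  expect_equal(sum(minor > 0 & ni > 0), nrow(sc2))
  expect_equal(sc2$i, as.integer(minor[minor > 0 & ni > 0]))
})

test_that("hypergeometric projection matches enumeration and preserves mean", {
  expect_equal(project_site(1, 4, 2), c(0.5, 0.5, 0))
  expect_equal(project_site(3, 8, 8), c(rep(0, 3), 1, rep(0, 5)))  # identity
  set.seed(2)
  for (rep in 1:30) {
    two_n <- sample(seq(2, 12, 2), 1)
    two_m <- sample(seq(2, two_n, 2), 1)
    i <- sample(0:two_n, 1)
    p <- project_site(i, two_n, two_m)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # expectation preserves allele frequency
    expect_equal(sum((0:two_m) * p) / two_m, i / two_n, tolerance = 1e-12)
  }
})

test_that("SFS projection is the identity at equal sizes and matches enumeration", {
  # all n_i = m: histogram of observed minor counts
  sites <- data.frame(i = c(1L, 1L, 2L, 5L), n_i = 5L)
  sfs <- project_sfs(sites, 5)
  expect_equal(sfs$counts, c(2, 1, 0, 0, 1))

  # two-site fixture vs full subset enumeration at 2m = 4
  sites2 <- data.frame(i = c(1L, 3L), n_i = 4L)
  sfs2 <- project_sfs(sites2, 2)
  expected <- numeric(2)
  for (k in seq_len(nrow(sites2))) {
    pj <- project_oracle(sites2$i[k], 8, 4)       # j = 0..4
    folded <- c(pj[2] + pj[4], pj[3])             # j=1+j=3, j=2
    expected <- expected + folded
  }
  expect_equal(sfs2$counts, expected, tolerance = 1e-10)

  # monomorphic leakage: total mass <= site count; linearity in subsets
  expect_lte(sum(sfs2$counts), 2)
  both <- project_sfs(rbind(sites, sites), 4)
  one <- project_sfs(sites, 4)
  expect_equal(both$counts, 2 * one$counts, tolerance = 1e-12)

  # sites below the target size are excluded and counted
  sites3 <- data.frame(i = c(1L, 1L), n_i = c(10L, 3L))
  sfs3 <- project_sfs(sites3, 5)
  expect_equal(sfs3$n_excluded, 1L)
})

test_that("MAF bins use inclusive upper bounds at the printed edges", {
  expect_equal(as.character(maf_bin(1, 1926)), "very_rare")  # 1/1926 <= 0.001
  expect_equal(as.character(maf_bin(2, 1926)), "rare")       # just above
  expect_equal(as.character(maf_bin(100, 2000)), "low")      # exactly 5%
  expect_equal(as.character(maf_bin(10, 2000)), "rare")      # exactly 0.5%
  expect_equal(as.character(maf_bin(1000, 2000)), "common")
})

test_that("FVRV fraction and Clopper-Pearson interval are exact", {
  # 2m = 2000: classes j = 1, 2 are very rare (MAF <= 0.001)
  counts <- numeric(1000)
  counts[1] <- 25; counts[2] <- 15   # very-rare mass 40
  counts[c(200, 500, 900)] <- 20     # 60 sites elsewhere
  sfs <- folded_sfs(counts, 1000)
  r <- fvrv(sfs)
  expect_equal(r$fraction, 0.40)
  expect_equal(r$ci_low, qbeta(0.025, 40, 61), tolerance = 1e-12)
  expect_equal(r$ci_high, qbeta(0.975, 41, 60), tolerance = 1e-12)

  # all singletons
  all1 <- folded_sfs(c(50, rep(0, 999)), 1000)
  r1 <- fvrv(all1)
  expect_equal(r1$fraction, 1.0)
  expect_equal(r1$ci_high, 1.0)

  expect_error(fvrv(folded_sfs(rep(0, 10), 10)), "empty")
})

test_that("Fisher tests match the hypergeometric enumeration oracle", {
  expect_equal(fisher_2x2(0, 0, 5, 9), 1.0)      # zero margin
  expect_equal(fisher_2x2(2, 8, 8, 2), fisher_oracle(2, 8, 8, 2),
               tolerance = 1e-9)
  expect_equal(fisher_2x2(3, 11, 7, 2), fisher_2x2(3, 7, 11, 2))  # transpose
  a <- fvrv(folded_sfs(c(10, rep(0, 1999)), 2000))
  b <- fvrv(folded_sfs(c(rep(0, 1999), 10), 2000))
  expect_equal(compare_fractions(a, a), 1.0)
  expect_equal(compare_fractions(a, b), compare_fractions(b, a))
  expect_lt(compare_fractions(a, b), 1e-3)       # (10,0 / 0,10) extreme
})

test_that("a rare-shifted category shows a higher FVRV than the neutral one", {
  cfg <- sim_config(
    n_samples = 60, n_sites = 6000, eps0 = 0, hwe_artifact_fraction = 0,
    category_props = c(intergenic = 0.5, nonsynonymous = 0.5),
    category_shift = c(intergenic = 0, nonsynonymous = 0.01),
    seed = 31)
  sim <- simulate_cohort(cfg)
  sc <- site_counts(sim$matrix)
  # at 108 projected chromosomes the rarest class is MAF 0.93%, so the
  # very-rare bound scales with the cohort: use 1% here
  m <- projection_size(60)
  vr <- 0.01
  f_neutral <- fvrv(project_sfs(sc[sc$functional_category == "intergenic", ], m),
                    very_rare = vr)
  f_shift <- fvrv(project_sfs(sc[sc$functional_category == "nonsynonymous", ], m),
                  very_rare = vr)
  expect_gt(f_shift$fraction, f_neutral$fraction)
  # monotone in the shift parameter
  cfg2 <- sim_config(
    n_samples = 60, n_sites = 6000, eps0 = 0, hwe_artifact_fraction = 0,
    category_props = c(intergenic = 0.5, nonsynonymous = 0.5),
    category_shift = c(intergenic = 0, nonsynonymous = 0.05),
    seed = 31)
  sim2 <- simulate_cohort(cfg2)
  sc2 <- site_counts(sim2$matrix)
  f_shift2 <- fvrv(project_sfs(sc2[sc2$functional_category == "nonsynonymous", ], m),
                   very_rare = vr)
  expect_gt(f_shift2$fraction, f_shift$fraction)
})
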