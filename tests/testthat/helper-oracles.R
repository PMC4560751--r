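# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms (explicit enumeration,
# direct combinatorial counting, coalescent simulation) from the code
# paths they validate.

# Exact HWE p-value by direct enumeration of genotype configurations:
# for fixed allele counts, the number of ways to realise h heterozygotes
# among n individuals is n! / (a! h! b!) * 2^h with a, b the implied
# homozygote counts. Weights are accumulated with plain products.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  n1 <- min(n_alt, 2 * n - n_alt)
  if (n1 == 0) return(1.0)
  h_vals <- seq(n1 %% 2, n1, by = 2)
  weight <- vapply(h_vals, function(h) {
    a <- (n1 - h) / 2          # rarer-allele homozygotes
    b <- n - a - h
    exp(lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1)) * 2^h
  }, 0.0)
  prob <- weight / sum(weight)
  p_obs <- prob[h_vals == n_het]
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

# Hypergeometric projection by exhaustive enumeration of every subset of
# two_m chromosomes out of two_n, i of which carry the allele.
project_oracle <- function(i, two_n, two_m) {
  chroms <- c(rep(1, i), rep(0, two_n - i))
  subsets <- utils::combn(two_n, two_m)
  j_counts <- apply(subsets, 2, function(idx) sum(chroms[idx]))
  as.vector(table(factor(j_counts, levels = 0:two_m))) / ncol(subsets)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- vapply(lo:hi, function(x)
    exp(lgamma(m1 + 1) - lgamma(x + 1) - lgamma(m1 - x + 1) +
        lgamma(m2 + 1) - lgamma(k - x + 1) - lgamma(m2 - k + x + 1) -
        (lgamma(m1 + m2 + 1) - lgamma(k + 1) - lgamma(m1 + m2 - k + 1))),
    0.0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kingman coalescent simulation under piecewise-constant diploid sizes:
# returns mean unfolded branch-length spectrum and its Monte-Carlo s.e.
coalescent_sfs_oracle <- function(sizes, durations, n, reps, seed) {
  set.seed(seed)
  bounds <- cumsum(durations)
  xi <- matrix(0, reps, n - 1)
  for (r in seq_len(reps)) {
    t <- 0
    desc <- rep(1L, n)
    while (length(desc) > 1) {
      k <- length(desc)
      need <- rexp(1) / (k * (k - 1) / 2)   # scaled hazard to next event
      t0 <- t
      repeat {
        ep <- findInterval(t, c(0, bounds))
        lim <- if (ep <= length(bounds)) bounds[ep] else Inf
        avail <- (lim - t) / (2 * sizes[ep])
        if (need <= avail) { t <- t + need * 2 * sizes[ep]; break }
        need <- need - avail
        t <- lim
      }
      elapsed <- t - t0
      for (d in desc) if (d < n) xi[r, d] <- xi[r, d] + elapsed
      pair <- sample.int(k, 2)
      desc <- c(desc[-pair], sum(desc[pair]))
    }
  }
  list(mean = colMeans(xi), se = apply(xi, 2, stats::sd) / sqrt(reps))
}
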