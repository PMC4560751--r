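# Small in-code fixtures and a memoised cohort-scale simulation shared by
# the acceptance checks (built once per test run).

toy_matrix <- function() {
  sites <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    is_known = c(TRUE, FALSE, TRUE),
    functional_category = c("intergenic", "intron", "nonsynonymous"),
    repeat_class = c("none", "Alu", "none"),
    stringsAsFactors = FALSE)
  genotype_matrix(
    genotype = rbind(c(0L, 1L, 2L), c(1L, NA, 0L), c(2L, 2L, 1L)),
    depth = rbind(c(30L, 25L, 40L), c(10L, 0L, 22L), c(33L, 28L, 31L)),
    sites = sites, samples = c("S1", "S2", "S3"))
}

# hand-built matrix + truth where concordance is fully controlled
controlled_truth_pair <- function(n_sites, depth, ngs, truth_gt) {
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(ngs, ncol = 1),
                        matrix(depth, ncol = 1), sites, "S1")
  tr <- array_truth(matrix(truth_gt, ncol = 1), "S1")
  rownames(tr$genotype) <- rownames(gm$genotype)
  list(gm = gm, truth = tr)
}

local({
  cache <- new.env(parent = emptyenv())
  cohort_fixture <<- function() {
    if (is.null(cache$sim)) {
      cache$sim <- simulate_cohort(sim_config(seed = 20260920))
      cache$res <- suppressWarnings(run_cascade(
        cache$sim$matrix, cache$sim$truth, cache$sim$sensitive_sites))
    }
    list(sim = cache$sim, res = cache$res)
  }
})
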