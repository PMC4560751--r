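---
title: "Methods: cohort variant QC, frequency spectra and tandem-gene copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort variant QC, frequency spectra and tandem-gene copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

panelforge implements the post-variant-calling computations needed to turn
raw genotype calls from deep whole-genome sequencing of a large cohort into
a high-confidence population reference panel, and the population-genetic
summaries built on top of it. This vignette is the package's account of the
models it implements, the tunable parameters that matter, the choices made
where the methodology was genuinely open, and what the synthetic cohort can
and cannot tell you about real data.

## The filter cascade

Raw per-sample genotype calls (coded 0/1/2 with per-cell read depth) are
cleaned in five ordered steps, numbered 2–6 because step 1 — alignment and
raw calling — happens upstream of this package:

1. **Per-sample depth calibration (step 2).** For each sample, calls at
   SNP-array-designed positions are grouped by integer read depth (capped at
   `depth_cap = 150`; bins with fewer than `min_bin_sites = 200` calls merge
   into the nearest lower bin, the bottom bin merging upward if it has no
   lower neighbour). Precision in a bin is the fraction of variant calls
   (het or hom-alt, at cells where the array reports) whose genotype equals
   the array genotype. The retained depth range is the longest contiguous
   run of bins with precision strictly above `depth_precision_min = 0.998`,
   ties broken toward the run with more calls. Genotypes at depths outside
   the inclusive range become missing. Samples with no passing bin are
   flagged uncalibratable and dropped, with a warning.
2. **Locus missingness (step 3).** Sites whose missing fraction strictly
   exceeds `max_missing = 0.10` are removed, so every surviving site has at
   least 90% of the cohort genotyped — which is also what makes the
   projection size below well-defined.
3. **Repeat-class precision (step 4).** Precision is pooled over samples
   per repeat-annotation class; classes at or below
   `repeat_precision_min = 0.997` are removed wholesale. Classes without
   array overlap are retained with a warning rather than guessed at.
4. **Caller intersection (step 5).** Sites absent from the
   high-sensitivity caller's superset are removed.
5. **Exact Hardy–Weinberg test (step 6).** Sites with exact-test
   p < `hwe_alpha = 1e-5` are removed. The test conditions on the observed
   allele counts (the Levene–Haldane distribution of the heterozygote
   count) and sums the probabilities of all heterozygote counts no more
   probable than the observed one; it is exact for rare variants where the
   chi-square approximation fails, and symmetric in the homozygote counts.

Boundary semantics are strict exactly as stated above: a bin at precision
0.998 fails step 2, a class at 0.997 fails step 4, a site at 10.0%
missingness survives step 3.

Two aspects of the depth calibration were open and are fixed here: the
retained set is a contiguous `[low, high]` interval (not an arbitrary union
of bins), matching the idea of cutting *extraordinarily low or high*
depths; and concordance is evaluated at genotype level (a het called hom-alt
is discordant), not merely at site level. A small-panel caveat follows from
the design: depth bins exist only where the truth set has cells, so with a
sparse truth panel the calibrated range cannot extend beyond the depths the
truth cells happen to cover. At realistic array densities (hundreds of
thousands of assayed sites per sample) this is immaterial.

## Folded spectra, projection and the very-rare fraction

Because the depth filter is per-sample, the number of genotyped individuals
varies by site. Each segregating site is summarised by its minor-allele
count `i` and callable size `n_i`, and projected to a uniform size of `m`
individuals with the hypergeometric projection

$$P(j \mid i, 2n_i, 2m) = \frac{\binom{i}{j}\binom{2n_i - i}{2m - j}}{\binom{2n_i}{2m}},$$

re-folding after projection and letting mass at `j = 0` leak out of the
segregating total. The projection target is `m = floor(0.90 * cohort)`
(963 for 1,070 individuals), which by construction of the missingness
filter equals the minimum callable size of any surviving site; sites with
`n_i < m` (possible only if the missingness filter was skipped or
reconfigured) are excluded and counted. Projection is linear, so per-category
spectra add to the total spectrum.

The fraction of very-rare variants (FVRV) of a spectrum is the share of its
mass at minor allele frequency at or below 0.1% — at 2m = 1926 chromosomes,
the singleton class. Higher FVRV in a functional category than in the
neutral intergenic baseline indicates stronger purifying selection. MAF
bins use inclusive upper bounds: very-rare ≤ 0.1% < rare ≤ 0.5% < low ≤ 5%
< common. Projected masses are fractional expectations; they are rounded
half-to-even to integers only where an exact test or binomial interval
needs integers, and the unrounded fraction is always reported alongside.
Computing FVRV on expected projected counts rather than on one random
downsample was an open choice; expectations were chosen because they are
deterministic and unbiased, at the cost of fractional counts. Intervals are
Clopper–Pearson (the conservative exact choice among "binomial" intervals),
and category comparisons use Fisher's exact test on the rounded 2×2 table.

Note the granularity constraint: the very-rare bin is non-empty only when
`2m >= 1000`. For small demonstration cohorts the `very_rare` bound should
be raised accordingly (the statistic is parametric in it); the default
matches the panel scale the package is built for.

## Demographic spectra, model fitting and discovery rates

Expected unfolded spectra under piecewise-constant population histories are
computed from coalescent branch-length expectations using the numerically
stable spectral recurrence in the sample size, with per-epoch closed-form
time integrals; exponential-growth epochs are discretised into 50
piecewise-constant slices. The constant-size case reduces to the classical
`xi_i ∝ 1/i` exactly, which is tested to 2,000 chromosomes; the variable
history case is validated against a brute-force Kingman coalescent
simulation in the test suite.

Model fitting maximises the multinomial composite log-likelihood of
observed folded class counts over the default family *ancestral constant
size plus a single recent exponential expansion*. Spectrum proportions are
invariant to an overall scaling of sizes and times, so only two ratios are
identifiable: the expansion fold `nu = N0 / N_anc` and the scaled onset
`t = T / (2 N_anc)`. The optimiser (Nelder–Mead over `(log nu, log t)` from
a 3×3 multi-start grid) therefore fixes `N_anc` at a reported reference
value (10,000 by default) and expresses the fitted model in those units.
For data generated without expansion the family is unidentifiable along
the ridge `t -> 0`, `nu ->` anything: the fitted *spectrum* still collapses
onto the constant-size spectrum, which is the meaningful null behaviour and
what the tests assert. At 10^5 sites, fold and onset of a 10× expansion are
recovered with median error well under 20%.

The discovery rate for a sequencing design of `n` individuals is the
probability that a variant of population MAF at least `f_min` is observed,
averaged over the model's folded frequency distribution `phi` evaluated on
a 20,000-chromosome reference grid:

$$R(f_{\min}, n) = \frac{\sum_{f \ge f_{\min}} \phi(f)\,\left[1 - (1-f)^{2n} - f^{2n}\right]}{\sum_{f \ge f_{\min}} \phi(f)}.$$

"Discovered" means at least one minor-allele copy in the sample (the
`f^{2n}` term removes samples monomorphic for the minor allele); requiring
`k ≥ 2` copies is available behind `min_copies`. The rate is invariant to
the normalisation of `phi` and monotone in both `n` and `f_min`.

The study's own demographic inference lives in unpublished supplementary
material, so the package ships a documented **stand-in** model for
simulation defaults: ancestral diploid size 10,000 with exponential growth
to 100,000 (10-fold) over the last 2,000 generations — generic recent-
expansion values for a large East Asian population, chosen once and not
calibrated against any published discovery-rate number.

## Tandem-gene copy number and the amylase diplotype model

Copy number over a named region is estimated from mean per-base read depth
normalised by half the depth of a mappability-selected diploid reference
region ("Region Z"), so diploid regions read 2.0 and the estimate is
invariant to a sample's global coverage. Mean per-base depth (rather than
raw read counts) removes region-length confounds; the diploid calibration
forces this reading. The three AMY1 gene loci are >99.9% identical and
cannot be resolved individually from short reads, so the quantity of
interest is the summed AMY1 diploid copy number `y` together with the copy
number `n` of the unique inter-gene unit region ("Region X"). Under the
haplotype structure (AMY1A–AMY1B)×k–AMY1C these satisfy the diplotype unit
model `y = 2n + 2`, checked by ordinary least squares of `y` on `n` with
95% parameter intervals. Integer calls round half-up, or to the nearest
even integer (ties down) when the two-gene copy unit is imposed. The
shipped hg19 region table follows the published coordinates verbatim, and
flags in its documentation that the AMY1A interval as printed is an order
of magnitude longer than AMY1B/AMY1C and overlaps the AMY2B interval; any
4-column BED can be substituted.

Structural-variant bookkeeping follows the published rules: calls with
reciprocal overlap ≥ 80% merge transitively into a unified call at the
half-up-rounded mean start/end of the members (output sorted, hence
order-invariant); an insertion is known if a catalogued insertion
breakpoint lies within 10 bp, a deletion if a catalogued deletion covers
at least half its length.

## Validation FDR

Each validated site is resolved from up to three assays: mass-spectrometry
genotyping, amplicon sequencing and Sanger arbitration. A no-call on either
primary platform makes the site a no-call unless Sanger (assumed truth)
rescues it; agreeing platforms decide; disagreeing platforms defer to
Sanger and otherwise yield a no-call; a lone reporting platform decides.
The FDR is `false / (true + false)` with no-calls excluded, with a
Clopper–Pearson interval, and the combined per-site estimate over known
and novel strata is `FDR_known * f_known + FDR_novel * (1 - f_known)` with
the convention `FDR_known = 0`. The published interval endpoints for the
validation FDRs are not reproducible under any single standard interval
named in the source text, so only point estimates are asserted anywhere in
this package.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates every input the pipeline consumes, fully
deterministic under its seed. Site frequencies are drawn from the folded
expected spectrum of the configured demographic model on a 2,000-chromosome
grid; per-category purifying selection is emulated by a geometric tilt of
that spectrum toward singletons (`weight ∝ exp(-sigma (j-1))`, `sigma = 0`
neutral) — one interpretable knob that reproduces the qualitative FVRV
ordering across categories. Genotypes are Hardy–Weinberg draws at the site
frequency; depths are negative-binomial (size 10) around per-sample means
centred on 32.4×; genotype errors replace the true code with a uniformly
chosen different code at a rate `eps0 = 1e-4` inflated 100× below depth 8
(1% — the calibration target of the depth filter), 20× above depth 120 and
30/20/30× in the Simple_repeat / Low_complexity / Satellite repeat classes.
A 1% fraction of sites carries planted excess heterozygosity
(`P(het) = min(1, 2pq + 0.9)`), the surrogate for reference-genome
artefacts the Hardy–Weinberg filter exists to remove. Array truth holds
error-free genotypes at 30% of common (MAF ≥ 5%) sites, with 5× lower
coverage of the high-error repeat classes — SNP arrays are designed on
common variants in non-repetitive sequence, and at desk scale (10^4 sites
rather than ~10^7) a repeat-heavy truth panel would drag every sample's
pooled precision below the 0.998 calibration threshold and make the
per-sample filter meaningless. The high-sensitivity superset contains every
true site plus 2% decoys. The amylase simulator plants a Poisson copy-unit
count with mean 3.135 — giving mean summed AMY1 copies 2·3.135 + 2 = 8.27,
the cohort mean the copy-number machinery is meant to operate around — and
Poisson read-count noise over the region lengths.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (no analysis in scope uses it), read-level artefacts
(alignment is upstream), allele-frequency-dependent genotyping error,
population substructure, and X/Y chromosomes. Passing tests therefore show
that the implementations are correct under the declared noise model — not
that the thresholds would reproduce the published per-step removal
fractions on the controlled-access cohort, which are data-dependent by
nature.

## Problem sizes and numerical choices

The test suite and acceptance script run the full cascade at the cohort's
nominal conditions (1,070 samples × 10,000 sites, a few tens of seconds);
enumeration oracles are exact up to 12 chromosomes (projection) and tables
of 25 (HWE); coalescent validation uses 15,000 replicates at 8 lineages;
demographic recovery uses 10^5 sites × 20 seeds at 200 chromosomes; copy-
number recovery uses 1,000 samples at 30×. Sums over projection classes
are exact binomial-coefficient ratios via `dhyper`; HWE probabilities are
computed in log space and normalised; probability-ordering comparisons use
a `1 + 1e-12` relative slack so ties in exact tests are included, as is
conventional. Zero-variance genotype vectors yield `NA` r² rather than an
error; all-missing sites keep an undefined HWE p and are retained with a
warning rather than silently removed.
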