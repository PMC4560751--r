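Package: panelforge
Title: Population Variant-Panel Quality Control, Site Frequency Spectra and
    Tandem-Gene Copy Number
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling toolkit for building a population reference
    panel from deep whole-genome sequencing of a large cohort. Implements a
    depth-calibrated genotype filter cascade validated against SNP-array truth
    (per-sample depth-range calibration, locus missingness, repeat-class
    precision, caller-intersection and exact Hardy-Weinberg filters), folded
    site-frequency-spectrum construction with hypergeometric projection to a
    uniform sample size, the fraction-of-very-rare-variants statistic with
    Clopper-Pearson intervals for purifying-selection comparisons across
    functional categories, expected spectra and variant discovery-rate curves
    under piecewise demographic models with SFS-based model fitting, read-depth
    diploid copy-number estimation for tandem gene arrays with the amylase
    diplotype unit model, validation-panel false discovery rate estimation, and
    a fully seeded synthetic-cohort generator so every stage is testable
    without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
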