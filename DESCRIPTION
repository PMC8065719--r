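Package: umivar
Title: UMI-Consensus Variant Calling and Analytical Validation for
    Targeted ctDNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A primer-anchored variant-calling pipeline for unique molecular
    identifier (UMI) tagged amplicon sequencing of circulating tumour DNA.
    Paired-end reads are merged with quality-based base correction, primers
    and UMIs are identified by fuzzy (edit-distance) matching, reads are
    collapsed into molecular families by majority vote, and consensus
    fragments are aligned to their panel reference windows with a
    multi-scheme semi-global aligner before whitelist-restricted variant
    tabulation. An analytical-validation suite computes sensitivity,
    specificity, predictive values and accuracy with exact Clopper-Pearson
    confidence intervals, scans variant-allele-frequency thresholds,
    condenses replicate calls, assesses reproducibility, and fits a logistic
    detection model to estimate the 90% limit of detection (LOD90). A
    synthetic reference-standard simulator generates UMI-tagged paired-end
    FASTQ libraries with spiked whitelist variants at configurable allele
    frequencies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
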