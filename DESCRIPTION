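Package: coveval
Title: Coverage Evenness and Variant-Calling Evaluation for Whole-Genome
    Sequencing Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark whole-genome sequencing platforms for
    coverage uniformity and variant-calling performance. Implements GC-bias
    quantification (log2 coverage in fixed-width windows, loess trend
    curves, Kolmogorov-Smirnov comparisons restricted to GC-poor and
    GC-rich regimes), per-base depth tracks with coverage histograms and
    downsampling/merging experiments, a census of uncovered regions
    stratified by genomic element (CpG islands, shores, promoters, introns,
    repeat classes), and coverage-thresholded ROC evaluation of SNV calls
    against a truth genotype set. Ships a synthetic genome/read/call
    simulator with platform profiles (fragment-GC response, coverage
    dispersion, mappability dropout, duplicates) so the full analysis runs
    without access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
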