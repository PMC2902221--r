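Package: cghloop
Title: Copy Number Variant Discovery from Dye-Swap Loop Array CGH
Version: 0.1.0
Authors@R: person("cghloop", "maintainers", email = "cghloop@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering copy number variants (CNVs)
    from two-color comparative genomic hybridization (array CGH) experiments
    laid out as a dye-swap loop design. Covers per-array spatial artifact
    removal by local regression on array grid coordinates, q-spline quantile
    normalization of channel intensities, exact least-squares segmentation of
    log2-ratio profiles by dynamic programming, dye-swap concordance and
    loop-design attribution of gains and losses to individual animals, merging
    of per-animal calls into copy-number-variable regions (CNVRs) with summary
    statistics, false-positive-rate estimation from sex-mismatched and
    self-self hybridizations, permutation tests for enrichment of CNVRs in
    genomic feature sets, and the scalar statistics used to characterise a CNVR
    catalogue (exact binomial, Wilcoxon rank-sum, dN/dS by CNV class). Includes
    a full synthetic-data generator (genome, probe tiling, loop design, planted
    CNVs, intensity artifacts) so that every stage is testable without array
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
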