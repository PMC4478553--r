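Package: arrayCNV
Title: Array-CGH Copy Number Variant Discovery, Validation, and CNVR Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale workflow for two-color array comparative genomic
    hybridization (aCGH) copy-number analysis: probe-level quality control,
    LOWESS intensity normalization, derivative-log-ratio-spread noise
    estimation, mode centralization, interval-score segmentation with a
    fuzzy-zero correction, post-filters for high-confidence CNV calls,
    aggregation of per-sample calls into cross-sample CNV regions (CNVRs),
    sex-mismatch false-positive estimation, qPCR 2^-ddCt copy-number
    confirmation accounting, gene overlap and dN/dS comparison, and UPGMA
    clustering of binary CNVR carrier profiles with bootstrap branch support.
    Includes a seeded synthetic-data generator producing probe maps, truth
    segments, noisy ratio tracks, sex-mismatched arrays, and qPCR Ct tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
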