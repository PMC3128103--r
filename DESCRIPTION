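Package: promodyn
Title: Promoter Tiling-Array Occupancy Dynamics, Co-Occupancy and
    Knockout Epistasis Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for promoter tiling-array ChIP data of the
    kind used to map stress-responsive chromatin factors: probe-level
    log2(ChIP/input) normalization by Tukey biweight centering, sliding-window
    peak calling with a within-promoter permutation null and step-down false
    discovery rate, calibration of FDR thresholds against known target lists,
    gene-level target mapping with knockout-control subtraction, temporal
    occupancy dynamics classification, transcription-factor co-occupancy
    statistics (log-space hypergeometric overlap, binding-site distances,
    knockout-dependence classes), rule-based epistasis classification of
    genotype-by-time expression profiles, and hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction. Includes a synthetic-data
    generator that plants oscillatory binding, co-occupancy structure and
    epistasis classes so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
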