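Package: cortexflat
Title: Cortical Flat Maps and Retrograde Tracer Quantification from
    Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantitative cortical connectivity
    mapping from multichannel histological section images. Detects
    NeuN-labeled neurons, classifies them as retrograde-tracer positive by
    integrated-intensity and peak-intensity thresholds, projects positive
    cells onto a smoothed layer IV/V reference polyline to build unrolled
    2D cortical flat maps anchored at the cingulum border, calibrates
    automated counts against manual counts by regression x-intercept
    offsets, aggregates region-of-interest counts into network proportions
    with injection-site zeroing, and compares injection groups with
    repeated-measures ANOVA and Bonferroni post-hoc tests. Ships a
    synthetic-histology generator with full ground truth so every stage is
    testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
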