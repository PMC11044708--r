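Package: sowlying
Title: Accelerometer-Based Lying-Behaviour Analysis for Lactating Sows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying lying behaviour of lactating sows from
    hind-leg accelerometers: per-sample lying classification of 1 Hz y-axis
    traces by a moving-median filter and a critical lying value, lying-bout
    extraction, parturition-aligned quarter-day summaries, reconciliation of
    sensor bouts against video ethograms by merging transitional sitting, and
    method-agreement validation with two-way random-effects intraclass
    correlation coefficients. Includes a semi-Markov ethogram simulator and a
    leg-angle sensor model so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
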