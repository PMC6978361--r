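Package: ndrscreen
Title: Normalized Drug Response Scoring for Cell-Based Drug Sensitivity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for high-throughput cell-based drug
    sensitivity screening built around the normalized drug response (NDR)
    metric, which uses start and endpoint viability readouts of drug-treated
    wells together with both negative (DMSO) and positive (benzethonium
    chloride) control conditions to correct for growth-rate differences and
    assay background. Includes the growth rate (GR) and percent inhibition
    (PI) metrics for comparison, four-parameter log-logistic dose-response
    curve fitting, drug sensitivity score (DSS) summarization, drug potency
    classification, plate quality control (Z'-factor, replicate and
    time-point consistency, overlapping coefficient), a ground-truth
    simulator of exponential-growth viability readouts, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
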