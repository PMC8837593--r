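Package: mtpa
Title: Multi-Timepoint Pattern Analysis of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("MTPA", "Developers", email = "mtpa@example.org", role = c("aut", "cre"))
Description: Estimates framewise time-varying functional connectivity between
    regional brain time series with flexible least squares (FLS), trains
    per-connection L2-regularized logistic classifiers that decode task versus
    rest from the temporal pattern of connectivity (multi-timepoint pattern
    analysis, MTPA), summarizes decoding accuracy at the level of large-scale
    brain networks with dice overlap of thresholded configurations, and relates
    per-subject task identifiability to behavioral measures via partial
    correlation with Bonferroni correction. Includes a synthetic-cohort
    generator with known ground-truth time-varying coupling so the whole
    pipeline is testable without access to restricted neuroimaging data, plus
    tab-separated readers/writers and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
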