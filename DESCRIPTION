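Package: satblot
Title: Quantitative Dot-Blot Hybridization Analysis of Tandem-Repeat Content
Version: 0.1.0
Authors@R:
    person("satblot", "developers", email = "satblot@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative non-radioactive
    hybridization (dot-blot) measurement of tandem-repeat abundance in genomic
    DNA, with satellite III (1q12) as the motivating assay.  Provides a
    synthetic membrane generator with a logarithmic intensity-content law and
    multiplicative noise stages, spot densitometry with local background
    correction, logarithmic standard-curve fitting and inverse prediction,
    triplicate aggregation with error estimates, repeat-content to copy-number
    conversion, cohort-level nonparametric statistics (Mann-Whitney U,
    two-sample Kolmogorov-Smirnov), paired pre/post therapy analysis, severity
    score association, and a multi-repeat brain-panel analysis with bimodal
    partitioning.  A command-line interface chains simulation, densitometry,
    calibration and statistics into a reproducible end-to-end run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
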