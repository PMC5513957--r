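Package: snarcpower
Title: Monte Carlo Power Analysis for SNARC Slope Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based power analysis for experiments that estimate the
    SNARC (Spatial-Numerical Association of Response Codes) effect with the
    classical dRT regression-slope method. Simulates bimanual reaction-time
    experiments from a slope-plus-lognormal-noise model, estimates per-subject
    SNARC slopes by ordinary least squares, and quantifies the power of
    one-sample tests for a within-group SNARC effect and of two-sample tests
    for a between-group slope difference across factorial grids of sample
    size, repetitions per item, slope magnitude and intra-individual
    variability. Includes a balanced factorial ANOVA on binary significance
    outcomes with partial eta squared effect sizes, and power-curve plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
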