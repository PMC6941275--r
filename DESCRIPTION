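Package: lagrisk
Title: Distributed Lag Non-Linear Case-Crossover Analysis of Daily Event Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for time-stratified case-crossover analysis of daily event
    counts against environmental exposures using distributed lag non-linear
    models (DLNM). Builds natural cubic spline cross-bases over the exposure
    and lag dimensions, fits quasi-Poisson regression with calendar-month
    stratum fixed effects, a population offset and a holiday term, and turns
    fitted cross-basis coefficients into exposure-response curves,
    lag-response curves and cumulative relative risks at extreme exposure
    percentiles with delta-method confidence intervals. Includes Q-AIC model
    comparison, Spearman-correlation collinearity screening for
    multi-pollutant models, subgroup and sensitivity analyses, and a
    synthetic daily-series generator with known ground-truth effect surfaces
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
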