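Package: isochron
Title: Timing Variability Analysis for Isochronous Rhythmic Movements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the temporal variability of isochronous
    rhythmic movements recorded by wrist accelerometry. Provides
    generators for event-based (two-level timekeeper) and emergent
    (autoregressive) timing processes and for full hierarchical study
    datasets; movement-interval extraction from tri-axial accelerometer
    traces; tempo-range ranking and fast/slow dichotomisation; per-set
    variability statistics (coefficient of variation, windowed lag-one
    autocorrelation with Fisher-Z summarisation and timing-mode
    classification); and heteroscedastic linear mixed models with
    factor-specific residual variances, variance-ratio estimation and
    likelihood-ratio testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
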