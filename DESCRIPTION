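Package: uaeopt
Title: Response-Surface and Neural-Network Optimization of Ultrasonic
    Extraction Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis of multifrequency ultrasonic-assisted
    extraction experiments. Builds Box-Behnken designs, fits full
    second-order response-surface models with ANOVA, lack-of-fit and
    adequacy diagnostics, trains small feed-forward neural-network
    surrogates with hidden-neuron selection, locates optimal extraction
    conditions with a real-coded genetic algorithm, and compares the
    prediction ability of the two surrogates (AAD, SEP, RMSE, R2).
    Ships a published 27-run seaweed polyphenol extraction study as a
    worked dataset and a synthetic-study generator with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
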