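Package: avalanchr
Title: Neuronal Avalanche Dynamics and Classification of ROI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects neuronal avalanches in source-reconstructed
    region-of-interest (ROI) time series, estimates branching ratios and
    avalanche transition matrices (ATMs), computes imaginary-coherence
    connectivity via DPSS multitaper cross-spectra, and classifies subject
    groups from edge features with a support vector machine under repeated
    stratified shuffle splits, including coefficient-based feature
    importance and signal-length (time-scale) analyses. A built-in
    branching-process cohort simulator with known propagation graphs makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    pROC,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
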