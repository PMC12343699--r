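Package: permclean
Title: Real-Time Anomaly Detection and Removal for In-Line Permittivity Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming detection and removal of spike and shift anomalies in
    in-line permittivity (capacitance biomass) sensor signals from fed-batch
    bioprocesses. Implements causal noise smoothing, a double rolling aggregate
    (DRA) context-removal transform, static and dynamic (3-sigma, Hampel/MAD,
    IQR) threshold detection, anomaly validation with merging, value
    replacement, and shift compensation via a cumulative correction factor.
    Ships evaluation metrics (NRMSE, cross-correlation delay, point-wise
    precision/recall/F1, parameter grid search) and a synthetic fermentation
    signal generator with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
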