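Package: grinfun
Title: Functional Profiling and Classification of NMDA-Receptor Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Turns raw electrophysiological and biochemical assay readouts
    for NMDA-receptor (GRIN) missense variants into quantitative functional
    profiles and gain-/loss-of-function calls.  Provides Hill-equation
    concentration-response fitting with log-space confidence intervals,
    biexponential deactivation analysis with amplitude-weighted time
    constants, MTSEA-potentiation open-probability estimation,
    reversal-potential screening for divalent permeability changes,
    beta-lactamase surface-expression quantitation, composite synaptic and
    non-synaptic charge-transfer scoring, a rule-based variant classifier,
    and a 3D-windowed missense-tolerance score over protein structures.
    A synthetic-data module simulates every assay with known ground truth
    so the full pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
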