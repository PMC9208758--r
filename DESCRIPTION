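Package: mufeedback
Title: Motor-Unit Biofeedback Task Engine and Spike-Train Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for closed-loop motor-unit (MU)
    biofeedback experiments. Provides a seeded motoneuron-pool generator with
    size-principle recruitment, rate saturation and de-recruitment hysteresis;
    recruitment/de-recruitment threshold estimation from trapezoidal force
    ramps; the buffered spike-rate-to-cursor task engine with target and
    angle-wedge geometry, hit, timeout and rest rules; trial-level performance
    metrics with best/worst normalisation, nearest miss, unintended hits and
    three-stage characteristic forces; two-source decomposition validation via
    discharge matching, rate of agreement and spike-triggered-average waveform
    pairing; and session-level nonparametric report statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
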