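Package: stopstate
Title: Stop-Signal Task Simulation and Motor Cortex State-Space Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses stop-signal / Go-only reaction time
    experiments probed with directional transcranial magnetic stimulation
    (TMS). Provides an independent horse-race trial engine with a
    staircase-tracked stop-signal delay, behavioral measures of proactive
    and reactive inhibition (response delay effect, p(inhibit), mean-method
    SSRT), preprocessing and 50-ms binning of motor-evoked potential (MEP)
    amplitudes into cue-locked and response-locked corticospinal
    excitability series, two-dimensional PA/AP state-space trajectories
    with Euclidean and cosine distance series, a bootstrap null of
    simulated Go-only trajectories, and linear mixed-effects inference
    with multivariate-t corrected post hoc contrasts.
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
    lme4,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
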