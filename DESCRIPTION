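Package: fnirsbci
Title: On-Line fNIRS Mental-State Detection and Working-Memory Load
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A passive brain-computer-interface pipeline for prefrontal
    functional near-infrared spectroscopy (fNIRS) recordings sampled at 2 Hz.
    Implements a calibration-free on-task/not-on-task state estimator based on
    streaming MACD (moving average convergence divergence) band-pass filtering
    and signal-line crossover detection, and a per-subject single-trial linear
    support-vector-machine classifier of working-memory load built on a
    sliding-window grid of 2352 amplitude and shape features. Includes modified
    Beer-Lambert conversion of raw two-wavelength intensities, chronogram
    scoring with onset/offset latency analysis, a synthetic session generator
    with canonical double-gamma hemodynamic responses and physiological noise,
    and an end-to-end train/test experiment orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
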