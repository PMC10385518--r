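Package: ssvepkit
Title: Decoding-Difficulty Grading and Benchmark Decoders for SSVEP Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Grades epoched steady-state visual evoked potential (SSVEP)
    EEG datasets by decoding difficulty using five indexes (narrowband and
    wideband signal-to-noise ratio, standard-algorithm recognition accuracy,
    optimal response time, and information transfer rate), maps them through
    five calibrated score functions to an A-E difficulty level, and ships
    the four benchmark frequency-recognition decoders the grading is tested
    against: canonical correlation analysis (CCA), filter-bank CCA (FBCCA),
    ensemble task-related component analysis (eTRCA) and task discriminant
    component analysis (TDCA). Includes a frequency-phase-coded synthetic
    SSVEP generator with controllable narrowband SNR, readers and writers
    for the public 4-D MATLAB epoch layout, and a leave-one-block-out
    cross-validation harness with paired-t algorithm comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
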