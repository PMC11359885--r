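Package: edanoise
Title: Noise-Elicited Electrodermal Activity: Simulation, Demodulation,
    Feature Extraction and Dose-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the effect of brief environmental noise
    stimuli on electrodermal activity (EDA) measured on three channels:
    skin conductance (SC), skin susceptance (SS) and skin potential (SP).
    Simulates graded noise-stimulus protocols and per-subject response
    features with random-intercept/random-slope structure, renders
    continuous component traces and the raw AC-carrier voltage of a
    current-source measurement, demodulates the carrier with a digital
    lock-in, extracts the five stimulus-locked response features
    (SCR/SPR/SSR amplitudes, SCR rise time and the SPRET statistic),
    estimates per-5-dB dose-response effects with repeated-measures
    ANOVA (Sidak post hoc) and a linear mixed model, and applies a
    binned correction that subtracts the estimated noise-elicited
    component from skin conductance response scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    minpack.lm,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
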