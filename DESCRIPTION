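Package: emodyn
Title: Dual-Model Analysis of EEG and PANAS Emotion-Regulation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying emotion regulation in immersive,
    EEG-instrumented settings. Generates synthetic participant cohorts
    and raw EEG segment pairs with controllable theta/gamma power
    shifts, extracts band-power change scores from pre/post recordings,
    scores the Positive and Negative Affect Schedule (PANAS), runs a
    nonparametric test battery with percentile-bootstrap confidence
    intervals, fits a quadratic/interaction regression of affect change
    on neural and self-report predictors, and simulates feedback-driven
    emotional payoff trajectories by projected gradient ascent on the
    fitted response surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
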