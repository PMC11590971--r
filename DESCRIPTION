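Package: fatiscope
Title: EEG-Driven Fatigue-Onset Labeling and Visual-Attention Analysis for Simulated Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting the onset of mental fatigue in
    simulated driving from parietal EEG alpha activity and relating it to
    visual attention. Implements individual alpha frequency (IAF) estimation
    from eyes-closed rest, strict-alpha parietal global field power (GFP),
    the MDrow drowsiness index, position-gated selection of paired low/high
    fatigue windows on the longest straight road segment, I-VT fixation
    classification with area-of-interest (AoI) visit metrics, and the
    accompanying statistical layer (Shapiro-Wilk gating, paired contrasts
    with Cohen's d, Friedman with Conover post hoc and Holm correction,
    mixed two-way ANOVA). A synthetic-session generator produces EEG, gaze,
    vehicle-trajectory and questionnaire streams with known ground truth so
    every stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
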