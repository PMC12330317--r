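Package: vpalign
Title: Simulation and Analysis of Visuo-Proprioceptive Alignment Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing visuo-proprioceptive
    cue-conflict alignment experiments. Builds deterministic trial schedules
    (veridical, gradual cue-conflict, and visual-shift control blocks),
    simulates a generative observer that integrates visual and proprioceptive
    cues by minimum-variance weighting and recalibrates trial by trial,
    generates synthetic short-latency afferent inhibition (SAI)
    neurophysiology coupled to proprioceptive recalibration, and implements
    the behavioural estimators (recalibration, cue weighting, 2D endpoint
    variance with indicator-hand correction), SAI quantification from motor
    evoked potential traces, and the inference stages (random-intercept
    multilevel regression with variance inflation diagnostics,
    repeated-measures ANOVA, group comparisons with Tukey HSD or
    Kruskal-Wallis, correlations, one-sample tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
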