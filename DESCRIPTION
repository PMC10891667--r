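Package: gaitinit
Title: Gait-Initiation Center-of-Mass Kinematics and Between-System Agreement
Version: 0.1.0
Authors@R: person("Biomechanics", "Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates whole-body center-of-mass velocity during gait
    initiation from two independent measurement chains (force-plate ground
    reaction forces integrated via Newton's second law, and positional
    differentiation of a center-of-mass trajectory), extracts the braking
    index and motor performance per trial, and quantifies between-system
    agreement with Bland-Altman limits of agreement, paired
    Jeffreys-Zellner-Siow Bayes factors with prior-robustness curves, and
    mixed-design repeated-measures analysis of variance with Tukey post hoc
    contrasts. Includes a physics-consistent synthetic gait-initiation
    cohort simulator with analytically known ground truth, zero-phase
    Butterworth filtering, CSV interchange formats and a command-line
    interface chaining the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
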