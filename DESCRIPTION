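Package: interceptvr
Title: Simulation and Analysis of Gaze, Kinematics and Appraisals in a
    Virtual-Reality Interception Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how pressure and failure feedback shape
    threat appraisals, anxiety and visuomotor performance in a
    virtual-reality racquetball interception task. Provides a synthetic
    session generator with known ground truth (ball flight with
    configurable restitution, gaze tracks containing pursuit, a
    predictive bounce fixation and catch-up saccades, swing kinematics,
    bogus hit/miss feedback schedules and probe self-reports), readers
    and writers for per-trial 90 Hz time-series files, zero-phase
    Butterworth and median filtering, trial segmentation and
    quality-control rules, acceleration-threshold saccade detection and
    dispersion-based (I-DT) fixation detection, per-trial dependent
    measures (interception outcome, bounce-fixation pitch and duration,
    peak swing velocity), and linear and logistic mixed-effects analysis
    recipes with standardized betas, marginal and conditional R-squared,
    Holm-corrected follow-ups and Monte-Carlo power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
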