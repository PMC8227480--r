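Package: nirswalk
Title: Block-Design fNIRS Cortical Activation Analysis for Gait Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing dual-wavelength block-design
    functional near-infrared spectroscopy (fNIRS) recordings acquired during a
    treadmill walking task. Implements channel quality control and subject
    exclusion rules, artifact removal, zero-phase Butterworth bandpass
    filtering, modified Beer-Lambert law inversion to oxy- and
    deoxy-hemoglobin concentration changes, the walking-block oxyhemoglobin
    area-under-curve biomarker aggregated per hemisphere, relative training
    intensity scoring for robot-assisted and overground gait rehabilitation,
    and the accompanying statistical battery (normality-gated two-sample
    tests, summary-statistic t-tests, mixed group-by-time ANOVA, Spearman
    correlations, chi-square contrasts). A synthetic-data generator with
    known ground truth stands in for clinical trial recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
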