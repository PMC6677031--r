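Package: tapmark
Title: Finger-Tapping Kinematics and Neuroimaging Biomarkers for REM
    Sleep Behavior Disorder Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mild motor impairment in REM sleep behavior
    disorder (RBD) from thumb-index finger-tapping distance waveforms:
    cycle segmentation, per-cycle amplitude and peak opening/closing
    speed, progressive-decrement slopes, and a normative two-standard-
    deviation classifier fitted on healthy controls.  Companion modules
    quantify dopamine-transporter SPECT uptake as specific binding
    ratios and left-right asymmetry indices over striatal volumes of
    interest, run ROI-to-ROI resting-state functional-connectivity group
    contrasts (band-pass, Pearson correlation, Fisher z, age/sex
    covariates, Benjamini-Hochberg false-discovery-rate control), and
    assemble the group-comparison and correlation report tables.  A
    synthetic cohort generator emulates the joint structure of all
    modalities so the full pipeline is reproducible and testable end to
    end without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
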