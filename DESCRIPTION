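Package: evspan
Title: Eye-Voice Span Analysis for Oral Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the eye-voice span (EVS) in oral reading of
    item lists: velocity-threshold (I-VT) detection of fixations, saccades,
    blinks and signal loss from high-rate gaze samples; assignment of
    fixations to rectangular areas of interest (AOIs) with first-pass gaze
    time, skip, accidental-entry and second-pass flags; onset EVS, offset
    EVS and gaze-time/processing-time (GT/PT) ratio computation with span
    classification and percentile crossing analysis; a fully accounted
    exclusion cascade; and crossed random-intercepts linear mixed models
    fitted by maximum likelihood with likelihood-ratio tests.  A synthetic
    gaze-and-voice generator reproduces the study design (grid stimulus
    lists, 1250 Hz scanpaths, voice-onset annotations, injected artifacts)
    with known ground truth, so every pipeline stage is verifiable without
    access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
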