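Package: emgcmc
Title: Muscle Individuation and Corticomuscular Coherence Analysis for
    EMG Biofeedback Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for at-home electromyography (EMG)
    biofeedback studies of wrist motor control after stroke. Implements
    the extensor-ratio (ER) muscle-individuation statistic from
    bandpass-filtered, rectified and maximum-grasp-normalized surface
    EMG; corticomuscular coherence (CMC) between sensorimotor EEG and
    Hilbert-envelope EMG using Welch magnitude-squared coherence with
    Hann windows, analytic confidence levels and Fisher/Stouffer
    beta-band summaries; a hemispheric laterality index; and pre/post
    group statistics (paired t-tests, Pearson correlation matrices with
    Benjamini-Hochberg adjustment, Stroke Impact Scale domain scores).
    Includes a synthetic EMG/EEG and clinical-score generator with
    programmable ground truth so every analysis stage can be verified
    without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    MASS,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
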