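Package: iscpipe
Title: Intersubject Correlation Analysis of EEG Responses to Naturalistic Video
Version: 0.1.0
Authors@R: person("iscpipe", "developers", role = c("aut", "cre"),
    email = "iscpipe@example.org")
Description: Tools for quantifying viewers' shared neural engagement with
    naturalistic video stimuli from multi-subject EEG.  Implements correlated
    component analysis (CorrCA), leave-one-out and time-resolved intersubject
    correlation (ISC), an EEG preprocessing chain (band-pass filtering,
    bad-channel zeroing, ICA-based ocular artifact removal, outlier zeroing,
    z-scoring, clip-onset excision), dual-threshold pose-keypoint movement
    annotation, an average-luminance-difference (ALD) visual-dynamics
    covariate, and a moderated linear mixed-effects engagement model with
    Satterthwaite degrees of freedom and Wilcoxon/Bonferroni post-hoc tests.
    A synthetic-data module generates multi-subject EEG, keypoint tracks and
    frame stacks with known ground truth so the whole pipeline is testable
    without access to raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
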