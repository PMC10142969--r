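Package: octenrich
Title: Predicting Suboptimal Anti-VEGF Loading-Phase Response from OCT
    Volumes and Clinical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-modal prediction of suboptimal anatomical response to the
    aflibercept loading-phase in neovascular age-related macular degeneration,
    and evaluation of AI-driven clinical-trial cohort enrichment. Provides a
    synthetic generator for layered-retina OCT B-scan volumes and clinical
    cohorts; treatment-protocol classification and patient-level stratified
    splitting; deterministic volume standardisation and clinical feature
    normalisation; Daubechies-1 wavelet edge maps, composite retinal
    foreground detection and per-volume affine augmentation; 2.5D residual
    and 3D convolutional image classifiers, an FFT + lasso scan classifier
    and an L2-regularised clinical logistic regression; score stacking with
    forward feature selection; AUROC/operating-point evaluation with
    bootstrap confidence intervals and univariate association testing; and
    emulation of trial candidate selection with enrichment metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    jsonlite,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
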