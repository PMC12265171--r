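Package: deepsuvr
Title: Trajectory-Constrained Correction of Amyloid-PET SUVR and Centiloid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies amyloid-PET scans on the Centiloid scale and learns a
    per-scan SUVR correction factor from longitudinal consistency constraints.
    A small 3D convolutional network predicts a correction factor in [0,2]
    from a spatially and SUVR-normalised volume plus the tracer code; training
    penalises Centiloid decreases over time, deviations from a lowess natural
    history curve of amyloid accumulation, and drift from the uncorrected
    Centiloid scale. Also derives data-driven reference and target masks by
    gradient descent so that mask-based SUVRs track the corrected SUVRs,
    provides the associated evaluation statistics (two-component Gaussian
    mixture peaks, Hilbert-Schmidt Independence Criterion, paired bootstrap,
    outlier-band fractions, effect sizes, AUC), and ships a synthetic phantom
    cohort generator so the whole pipeline is exercisable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
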