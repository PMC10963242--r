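Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Photoplethysmogram Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating systolic, mean arterial and
    diastolic blood pressure from single fingertip photoplethysmogram (PPG)
    segments. Provides skewness-based signal quality screening, min-max
    normalization and a low-pass filter bank (Butterworth, moving average,
    FIR, wavelet denoising), beat detection with best-cycle selection, a
    48-slot characteristic feature extractor covering the PPG waveform, its
    first and second derivatives and its spectrum, correlation-based (CFS)
    and ReliefF feature selection, four nonlinear regressors (support vector,
    random forest, decision tree and k-nearest-neighbour regression) with
    subject-grouped cross-validation, and device-grading statistics (AAMI
    compliance, BHS grades, Bland-Altman agreement). A synthetic PPG cohort
    generator with known landmark and blood-pressure ground truth makes every
    stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    ranger,
    rpart,
    caret,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
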