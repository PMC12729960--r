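Package: fatiguecg
Title: Three-Level Physical Fatigue Classification from Single-Lead Wearable ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying physical fatigue (normal,
    slight fatigue, fatigued) from single-lead wearable ECG recordings labelled
    with Borg 6-20 ratings of perceived exertion. Provides ECG preprocessing
    (baseline-wander removal, powerline moving-average filtering, 0.5-40 Hz
    bandpass, SNR-based artifact rejection), Pan-Tompkins R-peak detection,
    ultra-short-term HRV feature extraction (11 time-domain, frequency-domain
    and Poincare features), interpretable threshold/rule/weighted-score
    baselines, classical machine-learning classifiers, a hybrid CNN-BiLSTM
    deep model trained on raw 30-s segments, 1-D Grad-CAM interpretability,
    and an evaluation suite with segment-, session- and subject-wise splits,
    stratified cross-validation and McNemar paired tests. A synthetic
    wearable-ECG study generator with class-conditioned heart-rate and HRV
    structure and exported ground truth makes every stage testable without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    randomForest,
    nnet,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
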