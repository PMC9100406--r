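Package: gaitdx
Title: Gait-Based Identification of Diabetic Neuropathy and Foot-Ulcer
    History from EMG and Ground Reaction Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying control, diabetic-neuropathy
    (DN), and diabetic-foot-ulcer-history (DFU) subjects from lower-limb
    surface EMG (gastrocnemius lateralis, vastus lateralis, tibialis
    anterior) and three-dimensional ground-reaction-force signals recorded
    during gait. Includes a synthetic gait-cohort generator emulating the
    class effects reported in the clinical literature (delayed
    muscle-activation peak, reduced second vertical-GRF peak), zero-phase
    Butterworth signal conditioning with vertical-GRF stance segmentation,
    time-domain EMG features, time/frequency/wavelet GRF feature banks,
    four filter-type feature-ranking algorithms (chi-square, mRMR, ReliefF,
    neighborhood component analysis), correlation-based feature pruning,
    SMOTE class balancing, a distance-weighted k-nearest-neighbour
    classifier with subject-wise cross-validation, and macro-averaged
    evaluation metrics with one-vs-rest ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
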