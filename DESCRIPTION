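Package: absrad
Title: Pre-Treatment Radiomics and Blood-Count Prediction of the Abscopal Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for predicting the abscopal effect (systemic regression of a
    non-irradiated tumor after localized radioimmunotherapy) from pre-treatment
    imaging and blood counts in bilateral syngeneic murine tumor models. The
    package extracts a 92-feature volumetric radiomics catalogue (geometric,
    128-bin first-order histogram, second-order co-occurrence, and third-order
    collinear-triplet joint-probability texture including the information
    measure of correlation) from CT and intensity-normalized MRI tumor
    segmentations, derives blood-count ratios such as the
    neutrophil-to-lymphocyte ratio, labels the abscopal response from bilateral
    caliper growth curves, screens features by one-way ANOVA with a Pearson
    decorrelation filter, and fits ridge-stabilized binary logistic models
    evaluated by ROC/AUC with untruncated Hanley-McNeil confidence intervals.
    A synthetic-cohort generator produces NIfTI phantoms, blood panels, and
    growth curves with planted group effects so the whole pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    readxl
Config/testthat/edition: 3
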