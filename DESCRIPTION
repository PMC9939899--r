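Package: dynradiomics
Title: Dynamic Radiomics of Multi-Phase Contrast-Enhanced CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of dynamic radiomics features from
    multi-phase contrast-enhanced CT of liver lesions. Extracts first-order,
    shape and grey-level co-occurrence texture features per vascular phase
    (precontrast, arterial, portal venous, delayed), converts them into five
    classes of dynamic features summarising phase-to-phase change (standard
    discrete, discrete change, relative change rate, relative average change
    rate and polynomial-coefficient features), screens them by Welch t-test
    and LASSO, evaluates treatment-response prediction by leave-one-out
    cross-validation with LDA, linear SVM and random forest, and builds a
    progression-free-survival risk score from a random survival forest with
    Kaplan-Meier, log-rank and time-dependent ROC summaries. Ships a synthetic
    multi-phase cohort generator (feature level and voxel-level phantoms) so
    the whole workflow is testable without patient data, plus exact
    contingency-table tests for baseline characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    glmnet,
    randomForest,
    ranger,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
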