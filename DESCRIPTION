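Package: fastegm
Title: Focal-Source Detection and Deep Classification of Atrial Fibrillation Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting putative atrial-fibrillation focal sources
    (FaST sites) from paired 5-second unipolar/bipolar intracardiac
    electrograms. Implements the rule-based hierarchical FaST algorithm
    (bipolar spectral periodicity, graph-search activation annotation,
    unipolar QS morphology classification), a 1-D residual convolutional
    network classifier trained on raw unipolar traces with classic
    machine-learning baselines, gradient-weighted class-activation (Grad-CAM)
    importance traces, ROC/operating-point evaluation with patient-level
    cross-validation, and a fully annotated synthetic electrogram generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    signal,
    class,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
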