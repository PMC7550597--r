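Package: catrans
Title: Automated Abnormality Assessment of Cardiomyocyte Calcium Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic assessment of single-cell calcium transient
    fluorescence signals from human induced pluripotent stem cell derived
    cardiomyocytes. Detects transient peaks by sequential first-derivative
    screening, quantifies fourteen peak-level variables, applies a rule-based
    analytical algorithm for peak and cell abnormality (amplitude, asymmetry
    and irregular-phase rules), and trains a cascade of peak-level and
    cell-level support vector machine classifiers validated by
    leave-one-signal-out cross-validation. Includes confusion-matrix and
    ROC/AUC evaluation, a seeded generator of synthetic transient traces with
    ground-truth labels, and a command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    pROC,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
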