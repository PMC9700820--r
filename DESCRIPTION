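Package: ctphase
Title: Contrast-Phase Recognition for Multiphase Liver CT
Version: 0.1.0
Authors@R:
    person("ctphase", "developers", email = "ctphase@example.org",
           role = c("aut", "cre"))
Description: Image-based recognition of the contrast phase (unenhanced,
    arterial, portal-venous, delayed) of multiphase abdominal CT series,
    without relying on unreliable DICOM SeriesDescription metadata.
    Provides a synthetic multiphase abdominal phantom generator with known
    contrast kinetics and documented failure-mode confounders, a minimal
    DICOM Part-10 reader/writer, a configurable convolutional neural
    network slice classifier trained with categorical cross-entropy,
    Hyperband hyperparameter search, exam-level phase assignment by greedy
    bijective matching of volumes to phases, and a one-vs-rest evaluation
    suite (accuracy, precision, recall, F1, ROC AUC, confusion matrices,
    exam-level phase-correct summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
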