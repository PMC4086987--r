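Package: bbbensemble
Title: Inter-Patient Detection of Bundle Branch Block Heartbeats in Two-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies normal (NORM), left bundle branch block (LBBB) and
    right bundle branch block (RBBB) heartbeats in two-lead ECG under an
    inter-patient protocol: beats are segmented around annotated R peaks,
    z-normalized per lead, and described either by raw morphology plus the
    RR interval or by per-lead FastICA projections plus the RR interval.
    Three heterogeneous one-vs-one classifiers (a minimum-distance centroid
    classifier for NORM vs LBBB, a weighted linear discriminant with
    softmax posteriors for NORM vs RBBB, and a linear support vector
    machine for LBBB vs RBBB) are fused by majority vote with a NORM
    tie-break. Includes 10-fold cross-validated parameter selection with
    summed confusion matrices, the full sensitivity/predictivity metric
    suite, a minimal WFDB reader for MIT-dialect records, and a synthetic
    two-lead beat generator so the whole pipeline is testable without any
    database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
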