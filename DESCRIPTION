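Package: eegconn
Title: Quantitative EEG Band Power and Directed Brain Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative EEG analysis for studies of prolonged disorders of
    consciousness: preprocessing of multichannel scalp recordings (notch and
    zero-phase band-pass filtering, epoch-based artifact rejection), Welch
    band-power summaries including the delta-theta-to-alpha-beta ratio
    (DTABR), three connectivity estimators (band-limited Pearson correlation,
    pairwise Granger causality via vector autoregression, and phase transfer
    entropy on instantaneous phases), nonparametric group comparison
    (Mann-Whitney U with tie correction and exact enumeration, ROC/AUC with
    Hanley-McNeil confidence intervals), a synthetic cohort generator with
    known spectral and directed-coupling ground truth, and a reproducible
    two-cohort analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    lmtest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'eegconn-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'regions.R'
    'connectivity-edges.R'
    'epochs.R'
    'connectivity-granger.R'
    'preprocess.R'
    'connectivity-pearson.R'
    'connectivity-pte.R'
    'roc.R'
    'group-stats.R'
    'contrast.R'
    'synthetic.R'
    'spectral.R'
    'recording-io.R'
    'pipeline.R'
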