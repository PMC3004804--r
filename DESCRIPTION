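Package: cytobayes
Title: Laplacian-Modified Naive Bayes Modelling of Cytotoxicity Assay Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building binary cytotoxicity classifiers from
    heterogeneous high-throughput screening data. Implements the
    Laplacian-modified naive Bayesian learner over sparse circular-fingerprint
    features and binned physicochemical descriptors, activity labelling rules
    (fixed cutoff, top fraction, mean plus k standard deviations), ROC
    evaluation with k-fold cross-validation, activity-cutoff optimisation
    scans, Tanimoto chemical-space diagnostics, bidirectional assay
    cross-prediction networks for selecting datasets to merge into one
    general model, and a synthetic assay-panel simulator with planted
    structure-activity series for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
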