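Package: apofam
Title: Two-Tier Sequence-Based Classification of Apolipoproteins and
    Their Subfamilies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies apolipoproteins among plasma proteins and assigns
    positives to one of seven subfamilies, using only the amino-acid
    sequence. Provides four fixed-length sequence encoders (pseudo-amino-acid
    composition, k-spaced amino-acid pair composition, dipeptide composition,
    and a 188-dimensional composition/transition/distribution descriptor),
    ANOVA F-value feature ranking with incremental feature selection, and
    radial-basis-function support-vector classifiers tuned by grid search.
    Includes stratified cross-validated evaluation (sensitivity, specificity,
    accuracy, Matthews correlation coefficient, ROC/AUC), greedy
    identity-based redundancy reduction for benchmark curation, and a
    synthetic labelled-protein generator so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
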