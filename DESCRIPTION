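Package: pdvoice
Title: Grouped Out-of-Bag Random Forests for Voice-Based Parkinson's
    Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection pipeline for Parkinson's disease screening from
    per-recording audio feature tables. Implements subject-grouped,
    class- and gender-stratified bootstrap sampling for random forests so
    that out-of-bag validation respects repeated recordings of the same
    speaker, soft out-of-bag scoring from leaf class frequencies,
    decision-level stacking fusion across feature sets and modalities,
    detection metrics based on the ROC convex hull (equal error rate,
    minimum cost of the log-likelihood ratio, DET coordinates), forest
    proximity matrices with a 2D t-SNE embedding for decision support,
    and a synthetic cohort generator with subject random effects for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
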