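Package: immunorules
Title: Expression-Rule Discovery for Peptide Microarray Immunosignatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-class classification of peptide-microarray immunosignature
    profiles with interpretable expression rules. Implements Monte Carlo
    Feature Selection (relative-importance scoring over decision trees grown
    on random feature subsets and bootstrap resamples), a label-permutation
    cutoff for informative features, two-stage incremental feature selection
    wrapped around random-forest or one-vs-rest support-vector classifiers,
    rough-set Johnson attribute reduction, RIPPER ordered rule induction, and
    the Gorodkin multi-class Matthews correlation coefficient, plus K-nearest
    neighbour imputation of missing intensities and a synthetic
    immunosignature generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
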