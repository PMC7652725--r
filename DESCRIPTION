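Package: mdapred
Title: Microbe-Disease Association Prediction via Reliable Negatives and
    Neighborhood-Regularized Logistic Matrix Factorization
Version: 0.1.0
Authors@R: person("mdapred", "maintainers", email = "mdapred@example.org",
    role = c("aut", "cre"))
Description: Predicts microbe-disease associations from a sparse binary
    association matrix. Computes Gaussian association-profile similarities
    for microbes and diseases, fuses disease similarity with symptom-based
    cosine similarity, scores all pairs by random walk with restart on the
    heterogeneous microbe-disease network, extracts reliable negative pairs
    with a spy-based positive-unlabeled learning procedure, and fits a
    logistic matrix factorization model with K-nearest-neighbor
    graph-Laplacian regularization. Includes a three-scheme cross-validation
    harness (new microbes, new diseases, new pairs), a synthetic data
    generator with planted low-rank logistic structure, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
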