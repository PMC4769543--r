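Package: edgemarker
Title: Network-Guided Edge-Biomarker Discovery via Adaptive Elastic Net
    Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a sparse logistic regression whose features are per-sample
    expression products over the edges of a protein-protein interaction
    network, so that discriminative gene pairs (edge biomarkers) are selected
    rather than individual genes. Each edge coefficient carries an adaptive
    elastic-net penalty weighted inversely by the edge's degree in the line
    graph of the network, favouring interactions among highly connected
    genes. Provides a coordinate-descent solver over a warm-started
    regularization path, cross-validated selection of the penalty level and
    of the degree exponent, selection-stability protocols (soft and hard
    sample perturbation, between-dataset top-k overlap), a synthetic-data
    generator with planted informative edges, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
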