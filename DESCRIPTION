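Package: metdiffnet
Title: Differential Metabolite Network Analysis for Two-Group Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Univariate differential screening (fold change, Student's t-test,
    Benjamini-Hochberg false discovery rate with an external total-test count,
    volcano selection), partial least squares discriminant analysis with
    leave-one-out cross-validation and permutation significance, and a sparse
    local graphical model that infers common and condition-differential
    metabolite association networks from case/control metabolomics feature
    tables. Includes a synthetic two-group data generator with known planted
    effects and network structure, hypergeometric over-representation analysis
    against GMT metabolite-set libraries, and Cytoscape-compatible network
    export. Motivated by untargeted GC-MS urine metabolomics of interstitial
    cystitis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
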