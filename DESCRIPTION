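Package: secrank
Title: Manifold Ranking of Candidate Blood-Secretory Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transductive prioritisation of candidate blood-secretory
    proteins from protein feature tables using manifold ranking in a
    positive-unlabeled setting. Builds a Gaussian-kernel affinity graph
    over feature vectors, optionally sparsifies it by maximum-weight
    b-matching solved with loopy belief propagation, and propagates
    evidence from known secretory proteins (queries) over the
    symmetrically normalised graph to score every unlabeled protein.
    Includes a nearest-positive-distance prefilter for large candidate
    pools, a universal ranking variant that also uses known negatives,
    recall-precision evaluation with a query-subsampling benchmark
    protocol, SVM-based baseline rankers, and seeded synthetic
    positive-unlabeled data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
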