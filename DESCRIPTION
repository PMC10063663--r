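Package: simdims
Title: Sparse Non-Negative Matrix Factorization of Behavioral Similarity Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recovers low-dimensional, sparse, non-negative embeddings from
    pairwise similarity judgments of naturalistic stimuli. Implements sparse
    non-negative matrix factorization with Hoyer sparseness projection and
    NNDSVD initialization, a nested cross-validation scheme with elbow-based
    selection of the number of dimensions, a cross-validated PCA baseline,
    stimulus-perturbation robustness analyses with shuffle-based null
    distributions, odd-one-out dimension validation with omnibus
    sign-permutation testing, word-embedding label-agreement statistics, and
    synthetic-data generators with planted dimensions for end-to-end checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
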