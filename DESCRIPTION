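Package: galton
Title: Phylospatial Inference for Cross-Cultural Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing trait-environment hypotheses on cross-cultural
    data without being misled by Galton's problem: great-circle distance and
    spatial/phylogenetic covariance construction (exponential and Matern
    kernels, Brownian-motion tree covariance, hierarchical classifications),
    Moran's I and Mantel permutation diagnostics, a from-scratch logistic and
    Gaussian GLM, a latent-Gaussian spatial GLMM fitted by Laplace-approximate
    maximum likelihood, a synthetic-world generator with controlled spatial
    confounding, and an end-to-end reanalysis pipeline that reports whether a
    correlation survives spatial control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
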