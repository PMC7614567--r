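Package: orthopotts
Title: Coevolution-Based Design of Orthogonal Protein-Protein Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a global Potts (direct coupling analysis) model on a paired
    multiple sequence alignment of interacting protein families by Boltzmann
    machine learning with MCMC gradient estimation, scores cognate and
    cross-talk interactions through an intra/inter statistical-energy
    decomposition, generates candidate mutant pairs by temperature-controlled
    Metropolis sampling (direct and conditional variants with a fixed number of
    mutations per protein), and selects candidates predicted to be insulated
    from their native partners. Includes enrichment, embedding and diversity
    analyses of generated repertoires, synthetic ground-truth fixtures with
    exact enumeration oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    glmnet,
    pROC,
    jsonlite,
    optparse,
    Biostrings,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
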