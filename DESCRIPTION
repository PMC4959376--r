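Package: threeoff2
Title: Network Reconstruction from Categorical Data by Conditional 2-
    and 3-Point Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs partially directed graphical models (CPDAG-like
    networks) from finite categorical observational data with the 3off2
    scheme: indirect contributions to every pairwise mutual information are
    iteratively "taken off" as ranked conditional 3-point information terms,
    using normalized maximum likelihood (NML) or MDL/BIC finite-size
    corrections, and the resulting skeleton is partially oriented by the
    ranked likelihood of v-structures. Includes plug-in entropy and
    (conditional) mutual information estimators on sparse contingency
    tables, the universal multinomial normalization constant with its
    linear-time recursion and Szpankowski approximation, forward sampling
    from discrete Bayesian networks for simulation studies, DAG-to-CPDAG
    conversion, and orientation-aware precision/recall/F-score evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
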