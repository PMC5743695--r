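Package: elevdisp
Title: Phylogenetic and Functional Community Structure Along Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying phylogenetic and trait-based community
    structure along elevational gradients: standardized effect sizes of mean
    pairwise and nearest-taxon distances under a fixed-margin independent-swap
    null model, Blomberg's K and the Fritz-Purvis D statistic for phylogenetic
    signal, spatial eigenvector (PCNM) construction from a combined
    horizontal-plus-vertical geographic distance, forward variable selection
    and three-set variance partitioning of dispersion among environment, space
    and phylogeny, and elevational regressions of community-mean traits for
    assessing Bergmann's and Allen's rules. Includes a synthetic-data
    generator (Yule trees, Brownian traits, elevation-structured landscapes,
    and filtering / limiting-similarity / neutral community assembly) so the
    whole pipeline can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
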