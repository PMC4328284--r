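Package: morphorates
Title: Landmark Morphometrics, Disparity, and Phylogenetic Rates Across
    Ecological Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how major ecological transitions reshape
    morphological diversity on a time-calibrated phylogeny. Provides 3D
    landmark input with mirror-filling of one-sided missing data,
    generalized Procrustes superimposition with extraction of the symmetric
    shape component, species means and tangent-space principal components;
    range- and variance-based disparity with bootstrap confidence intervals
    and rarefaction; maximum-likelihood Brownian-motion and multi-optima
    Ornstein-Uhlenbeck (Hansen) model fitting with AIC comparison of
    painted regime hypotheses; the Independent Evolution estimator of
    ancestral states and branch-specific rates with time-sliced
    evolutionary morphospace export; and a synthetic-data generator that
    simulates trait evolution on birth-process trees by exact transition
    sampling and renders specimens as landmark configurations with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
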