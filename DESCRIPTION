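Package: mfi
Title: Model-Free Higher-Order Interactions via Moebius Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact model-free interactions (MFIs) among binary and categorical
    variables, computed as iterated Boolean derivatives of log joint probability
    and, equivalently, as Moebius inversions of background surprisal on subset
    and chain-product lattices. Includes higher-order and dual (differential)
    mutual information, generalized pointwise mutual information, Boltzmann/Ising
    constructors whose couplings the MFIs recover exactly, noisy logic-gate and
    dyadic/triadic fixture distributions, a causal-DAG simulator with an
    association-metric comparison panel, and a small command-line interface.
    Tables in, tibbles out: joint distributions, interaction scans and panels
    are plain tabular objects that compose with the tidyverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
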