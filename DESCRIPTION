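Package: cenozone
Title: Biotic Assembly of Transition Zones from Cenocrons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the biotic assembly of biogeographic transition
    zones from evolutionary biotic units (cenocrons). Classifies taxa into
    cenocrons with rule-based criteria from regional species tallies,
    computes spatial phylogenetic assemblage metrics (richness, pendant-age,
    node depth, Faith's phylogenetic diversity with a tip-shuffle null model,
    weighted endemism) from stacked binary ranges and a dated tree, detects
    the environmental transition zone where cenocrons overlap in principal
    component space, and diagnoses niche conservatism versus convergence from
    metric-environment correlations. Ships a synthetic-data generator
    (gradient landscapes, clade-structured ultrametric phylogenies,
    Ornstein-Uhlenbeck niche evolution, Gaussian-suitability binary ranges)
    so the full pipeline is testable against known generating regimes.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
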