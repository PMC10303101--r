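Package: autocmap
Title: Auto-Contractive Map Semantic Connectivity Analysis for Cardiometabolic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse cohort tables of clinical, anthropometric and hair
    trace-element variables with an Auto-Contractive Map (Auto-CM) neural network.
    Includes a seeded synthetic cohort generator with calibrated marginals and a
    planted latent-factor correlation structure; composite cardiometabolic indices
    (fatty liver index, visceral adiposity index, Framingham risk score, ATP III
    metabolic syndrome, hair toxicity index); dichotomization and min-max encoding;
    Auto-CM training with link-strength extraction; minimum-spanning-tree semantic
    connectivity maps with GraphML/DOT export; and an Activation and Competition
    System (ACS) for clamped steady-state perturbation analysis with activation
    hierarchies.
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
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
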