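Package: rhizonet
Title: Soil Microbiome Co-Occurrence Networks, Compositional Statistics and
    Yield Prediction for Field Trials
Version: 0.1.0
Authors@R:
    person("Biome", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline linking soil and rhizosphere microbiome
    composition and local co-occurrence network structure to treatment effects
    and crop yield in replicated field trials. Provides an exact probabilistic
    (hypergeometric) pairwise co-occurrence engine, metacommunity network
    construction with prevalence filters, per-sample local network properties
    (modularity, transitivity, edge proportions), Bayesian-multiplicative zero
    replacement, centered log-ratio transforms, Aitchison distances, PCoA,
    PERMANOVA, treatment-by-time interaction contrasts with
    Benjamini-Hochberg control, a probability forest yield classifier with
    Gini importances, and a synthetic study generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
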