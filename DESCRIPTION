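Package: macroniche
Title: Climatic Niche Divergence, Niche Evolution Rates and Clade Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative phylogenetic toolkit linking the climatic niches of
    species and clades to net diversification rates and species richness.
    Implements standardized climatic niche widths and niche positions from
    gridded climate data, method-of-moments net diversification estimators
    from clade stem age and richness, Brownian-motion and Pagel's-lambda
    maximum-likelihood rates of climatic niche evolution, phylogenetic
    generalized least squares with profile-ML lambda, forward stepwise
    predictor selection, commonality-based variance partitioning, resampling
    null models with spatially and climatically constrained species pools,
    fixed-stem-age clade slicing for robustness analyses, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    jsonlite
Config/testthat/edition: 3
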