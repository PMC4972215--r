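Package: phyloferm
Title: Comparative Phylogenetics of Cell Size and Fermentation Versatility in Budding Yeasts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-phylogenetics workflow for the Saccharomycotina
    (budding yeasts) relating cell size to fermentation versatility, the
    number of sugars (of seven commonly scored) a species can ferment.
    Provides phylogenetic-signal tests (a parsimony transition-count
    permutation test for the ordinal trait and Blomberg's K with a
    contrasts-variance randomization for the continuous trait),
    disparity-through-time curves with the morphological disparity index and
    its Brownian-motion simulation null, maximum-likelihood fitting of
    single-regime (BM, OU, early-burst, delta, white-noise) and multi-regime
    (BM1, BMS, OU1, OUM) trait-evolution models with AICc ranking and Akaike
    weights, pure-birth speciation-rate estimation from lineage-through-time
    data, penalized-likelihood time calibration, and phylogenetic generalized
    least squares with Pagel's lambda. A synthetic-data generator produces
    Yule trees, Mk-evolved ordinal traits, OU/BM-evolved continuous traits
    and phylogenetically correlated trait pairs so that every stage is
    verifiable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    phangorn,
    nlme
Config/testthat/edition: 3
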