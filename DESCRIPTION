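Package: charsat
Title: Rates, Constraint and Character-State Saturation on Phylogenies of Discrete Morphological Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rates and constraints of discrete
    morphological character evolution on time-calibrated phylogenies.
    Reads NEXUS character matrices (with polymorphic, missing and
    inapplicable scores) and MrBayes-style rate-annotated trees; computes
    maximum observable rescaled distances (MORD) between taxa and
    patristic morphological distances on trees whose branch lengths are
    expected character-state changes; fits Michaelis-Menten saturation
    curves to dissimilarity-versus-patristic-distance pairs and compares
    the asymptote against equal-rates null simulations with an 84%
    confidence-interval decision rule, including a scan over every node
    of the tree; summarises branch rates through time by 1-Myr slicing
    with Loess trends; and fits single- and multi-regime Mk models of a
    discrete trait (such as body-size category) with Akaike-weight model
    comparison, marginal ancestral-state reconstruction and forward
    simulation.  A synthetic-data module generates birth-death trees
    with fossil tips, constrained character matrices and regime-
    dependent traits with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    igraph,
    jsonlite
Config/testthat/edition: 3
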