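Package: traitscape
Title: Phylogenetic Trait Imputation and Trait-Based Biogeography of Gene Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic imputation of discrete traits (such as polyketide
    chemotypes) for uncharacterized tips of a phylogeny from a small set of
    annotated reference tips, using an equal-rates continuous-time Markov (Mk)
    model with pruning likelihoods and maximum-likelihood rate estimation.
    Includes the downstream community-level toolkit: tree-based sequence
    similarity binning (furthest-neighbor criterion), rarefaction, trait
    pseudo-abundance matrices, Bray-Curtis and normalized weighted UniFrac
    dissimilarities, Mantel and partial Mantel tests with log-log distance-decay
    slopes, ANOSIM, multiple regression on distance matrices, bioenv variable
    selection, a Faith's PD randomization test of phylogenetic trait clustering,
    and a synthetic-landscape generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    vegan,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    Matrix,
    optparse
Config/testthat/edition: 3
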