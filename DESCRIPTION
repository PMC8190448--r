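Package: floradiverge
Title: Community Assembly and Macroevolutionary Divergence of Floral Traits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test how flower colour, floral morphology and flowering
    phenology are distributed across ecological communities and across a dated
    phylogeny, in order to discriminate speciational, allopatric-divergence and
    negative-interaction models of floral trait evolution. Implements
    organ-weighted colour profiles with exact earth-mover (transportation)
    distances, circular statistics for flowering phenology, functional richness
    (FRic) and mean pairwise phylogenetic distance (MPD) with independent-swap
    and dispersal null models, phylogenetic signal (Blomberg's K, Pagel's
    lambda), BM/OU/white-noise model selection by AICc, disparity-through-time
    with Brownian-motion envelopes, lineage-through-time curves, branch-specific
    trait rates by phylogenetic ridge regression, the inverse equal-splits
    diversification-rate proxy, and a Laplace-approximated phylogenetic mixed
    model of log trait rate on diversification rate and branch age with
    Bayes-factor model comparison. A seeded synthetic-data module generates
    trees, traits, colour profiles, phenology and communities under three
    competing evolutionary models so that every stage is testable without field
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    matrixStats,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    nlme,
    mvtnorm,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
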