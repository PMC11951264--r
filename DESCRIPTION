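Package: hfadecomp
Title: Home-Field Advantage Analysis for Reciprocal Litter-Transplant Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying the home-field advantage (HFA) of leaf-litter
    decomposition in reciprocal transplant microcosm experiments, and for linking
    HFA to soil fungal community dissimilarity. Implements litter mass-loss and
    HFA indices (net two-species index and per-species mean HFA), Bray-Curtis and
    per-taxon log-ratio dissimilarity between home and away communities, read
    quality filtering, rarefaction, taxonomic aggregation and trophic-guild
    assignment for ITS OTU tables, and an inference layer (principal coordinate
    analysis, PERMANOVA, one-way ANOVA with Bonferroni post-hoc, t-tests,
    assumption gating, and single and multiple regression of mean HFA on
    dissimilarity predictors). A synthetic-data generator reproduces the full
    two-phase factorial design - exponential decay with a home-affinity term and
    a late-stage glucose boost, plus Dirichlet-multinomial fungal communities
    with soil-source separation, temporal succession and a glucose-driven
    composition shift - so the complete pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
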