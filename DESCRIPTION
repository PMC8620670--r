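Package: alienflora
Title: Phylogenetic Structure of Alien, Naturalized and Invasive Floras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing regional checklists of alien vascular plants
    along the introduction-naturalization-invasion continuum. Derives the
    nested alien / casual / naturalized / naturalized-but-not-invasive /
    invasive assemblages from a single highest-stage status column, tabulates
    family, lifeform, origin and introduction-pathway composition, and
    quantifies phylogenetic structure: mean nearest taxon distance (MNTD),
    the nearest taxon index (NTI) as a standardized effect size against a
    richness-maintaining null drawn from the alien reference pool,
    between-assemblage nearest-taxon distances (comdistnt), and principal
    coordinates ordination of the resulting distance matrix. Includes a
    synthetic-data generator (Yule trees, clade-biased and maximin assemblage
    samplers, checklist simulation) so every stage of the pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    picante,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
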