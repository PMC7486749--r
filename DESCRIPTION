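Package: lipidisc
Title: Discriminant Analysis of Lipidomes for Keratinocyte Differentiation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of shotgun lipidomics data and plate-based
    siRNA screens, built around the question of which individual lipid species
    accompany exit from the epidermal stem cell compartment. Provides a lipid
    species nomenclature parser, mol percent normalization, class composition,
    hierarchical clustering and PCA, a from-scratch sparse partial least
    squares discriminant analysis (sPLS-DA) with per-component keepX variable
    selection, loading-threshold plus enrichment rules for nominating
    discriminant lipid species across experiments, modified Z-score scoring
    and volcano-style hit calling for 96-well siRNA screens, and a synthetic
    data generator with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    caret,
    cluster
Config/testthat/edition: 3
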