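Package: mitonuc
Title: Respirometry, Robust Group Statistics and KA/KS Analysis for
    Mito-Nuclear Introgression Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of mito-nuclear
    introgression experiments in Drosophila: closed-flow respirometry
    metabolic-rate calculations (VO2, VCO2, respiratory quotient,
    per-fly normalization and block-reference scaling), a decision-tree
    statistics layer (Cook's-distance influence filtering, Shapiro/Levene
    gated two-group tests with an HC4 heteroscedasticity-robust OLS path,
    Holm-Bonferroni families, Hedges' g, Type-III factorial ANOVA with
    omega-squared effect sizes and power), a codon-level KA/KS module with
    degeneracy site classes and Kimura two-parameter corrections,
    neighbor-joining trees with bootstrap support, and synthetic-data
    generators with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
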