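Package: metabomat
Title: Linking the Latex Metabolome to Natural-Rubber Material Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of latex metabolomics and natural-rubber
    material characterization. Provides seasonal differential screening of
    metabolite abundances (fold-change plus exact one-tailed Mann-Whitney
    tests), metabolite-by-property Spearman correlation structure with
    hierarchical clustering and Kruskal-Wallis contrasts across property
    groups, a three-model regression framework (simple-regression best model,
    forced-entry minimum-norm model, sequential forward floating selection)
    scored by leave-one-out cross-validation with IQR-normalized errors,
    overlap counting of selected metabolites per property group, and
    chemical-structure diversity quantification via circular (Morgan)
    fingerprints embedded with UMAP. A synthetic-data generator with planted
    seasonal effects and planted linear property supports makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite,
    uwot
SystemRequirements: Open Babel (the obabel executable, for fingerprints)
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
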