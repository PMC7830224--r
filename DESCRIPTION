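Package: panelora
Title: Gene-Panel Over-Representation Analysis, Ontology Knowledge
    Reduction, and Variant Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Functional characterization of targeted gene panels through
    Gene Ontology style over-representation analysis with Fisher's exact
    test and Bonferroni control, followed by knowledge reduction of the
    significant term polyhierarchy: remarkableness scoring (certainty times
    Shannon-style information), computed ABC item categorization, per-branch
    headline selection, and subsumption of headlines into a human-graspable
    set of functional areas. Also provides quality control and description
    of amplicon-panel variant output: Hardy-Weinberg equilibrium filtering,
    variant location classification against gene models, per-base coverage
    acceptance, and robust percentage-bend correlation of variant counts
    with gene length. A synthetic-data module generates ontologies with
    planted enrichment, genotype matrices under or violating Hardy-Weinberg
    equilibrium, and length-correlated variant tables with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
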