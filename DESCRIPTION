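Package: proteosig
Title: Proteostasis-Network Signatures of Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the involvement of the proteostasis network (PN) in
    disease gene sets and derives disease-level proteostasis signatures.
    Provides hypergeometric over-representation analysis of protein groups
    and PN pathways, classification of diseases into proteostasis
    perturbation states from their UPS and extracellular enrichment
    pattern, Jaccard-similarity hierarchical clustering with gene-wise
    consensus signatures, empirical-Bayes moderated-t differential
    expression for stage-vs-control contrasts, perturbation-onset and
    stage-proportion analysis, interaction-network centrality summaries,
    and directional similarity scoring of risk-factor exposures against
    disease panels. A seeded synthetic-data generator with planted,
    recoverable structure makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
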