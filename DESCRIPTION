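Package: modnet
Title: Quantification and Network Analysis of Genetic Modifier Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for Drosophila genetic modifier screens of
    neurodegeneration phenotypes. Quantifies suppression and enhancement
    from eye-surface areas, eclosion-based viability (normalized lethality)
    and climbing assays, and classifies modifier strength from
    per-time-point significance. Performs term-enrichment analysis with
    true-path annotation propagation, elimination-based de-correlation of
    the ontology graph, exact hypergeometric tests and Benjamini-Yekutieli
    false-discovery-rate control. Builds typed interaction subnetworks for
    gene lists and tests their mean node-degree and mean node-betweenness
    against a random-gene-list permutation null with Z-scores and fold
    enrichments. Maps gene lists across species by consensus orthology
    votes with a minimum-score filter and disease-annotation joins. A
    seeded synthetic-data module generates interactomes with a planted
    dense module, small ontologies with a planted enriched term, and
    screen tables with genotype-dependent means, so the whole pipeline is
    testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
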