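Package: cernasponge
Title: Prioritization of circRNA-miRNA-mRNA Sponge Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: File-driven construction and prioritization of competing endogenous
    RNA (ceRNA) networks from circRNA-to-miRNA sponge maps and validated
    miRNA-to-gene target maps. Selects hub miRNAs by sponge in-degree with fixed
    or elbow-derived frequency cutoffs, reverse-searches the circRNAs most
    recurrently targeting those hubs, performs hypergeometric overrepresentation
    analysis of target genes against pathway collections with Benjamini-Hochberg
    false-discovery-rate control, categorizes enriched pathways by keyword,
    cross-references relevant genes with a risk-gene catalog, assembles the
    tripartite circRNA-miRNA-gene network, and identifies circRNAs whose sponged
    miRNAs jointly cover a designated target gene set (full-coverage and minimum
    set-cover analysis). Includes a synthetic interactome generator with planted
    ground truth (hub miRNAs, full-cover circRNAs, enriched pathways) so every
    pipeline stage is testable without live database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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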