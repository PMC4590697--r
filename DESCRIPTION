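Package: netage
Title: Integration of New Genes into Gene-Gene Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how genes of different evolutionary ages are
    embedded in gene-gene interaction networks. Builds confidence-thresholded
    protein-protein interaction networks and Pearson-correlation co-expression
    networks from tabular inputs, attaches phylogenetic-branch ages to genes,
    computes degree and betweenness centralities, power-law degree-distribution
    fits, hub flags and core/periphery layers, and derives age-stratified
    integration profiles (centrality versus divergence time, interaction
    acquisition rates, layer occupancy, expression breadth). Quantifies partner
    inheritance of duplicate gene pairs against a random-pair null and tests
    preferential attachment of young genes' new links toward high-centrality
    and older partners. A duplication-divergence plus preferential-attachment
    network growth simulator supplies synthetic inputs with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
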