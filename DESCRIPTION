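Package: cernet
Title: Competing Endogenous RNA Network Inference from Methylation and
    Expression Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate lncRNA biomarkers by integrating two-group
    gene expression and DNA methylation screens into aberrantly
    methylated-differentially expressed gene classes, inferring
    mRNA-miRNA-lncRNA competing triplets with a cumulative hypergeometric
    shared-miRNA test plus Pearson co-expression filtering, and ranking
    lncRNAs by degree and betweenness in the resulting tripartite network.
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads, a generic hypergeometric
    over-representation stage for gene-set enrichment, and readers/writers
    for TSV matrices, edge lists, GMT collections, SIF and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
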