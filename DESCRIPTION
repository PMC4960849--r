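Package: proteotypeR
Title: Metaproteome Proteotyping of Anaerobic Digester Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spectral-counting proteotyping pipeline for multi-sample
    metaproteome surveys of microbial communities, modelled on large-scale
    biogas-plant studies. Peptide-spectrum-match tables are filtered,
    annotated by homology transfer, grouped into UniRef50 "metaproteins"
    with common-ancestor taxonomy, and turned into relative-abundance
    matrices at the metaprotein, taxonomic-order, biological-process and
    pathway levels. Downstream analyses cover core-community extraction,
    richness and Gini-based evenness, z-score hierarchical clustering with
    a permutation test for group separation, principal component analysis,
    Spearman correlation networks of features against process parameters
    (exported as GEXF graphs), and CART decision-tree discovery of marker
    metaproteins for process conditions. A synthetic-study generator with
    planted group structure, parameter-feature correlations and marker
    features provides ground truth for end-to-end recovery tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rpart,
    withr
Config/testthat/edition: 3
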