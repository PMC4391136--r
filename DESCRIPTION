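Package: musiccr
Title: Marker-Gene Based Normalization of Metagenomic Functional Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts per-sample KEGG Orthology (KO) read abundances into
    average genomic copy numbers using universal single-copy marker genes
    (Inter-MUSiCC), corrects gene-specific abundance biases with an
    elastic-net regularized linear model on gene properties (Intra-MUSiCC),
    and provides marker selection from genome content matrices, sample
    property estimation (average genome size, richness, mappability),
    genome-size based alternative normalizations, a ground-truth mock
    community shotgun simulator, and a comparative-analysis layer
    (differential genes and pathways, coefficient-of-variation bootstraps,
    OTU-specific gene concordance, correlation-structure comparison).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
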