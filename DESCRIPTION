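Package: wtnet
Title: Genotype-Discriminating Microbiota Index and Co-Abundance Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16S rRNA OTU count tables comparing two host
    genotypes: rarefaction and alpha/beta diversity, Hellinger-transformed
    two-group redundancy analysis with key-OTU selection, a per-sample
    wild-type index with leave-one-out cross-validated ROC and bootstrap
    confidence intervals, SparCC compositional correlation networks with
    permutation edge significance and graph-topology comparison, supporting
    group statistics (Mann-Whitney with BH-FDR, MANOVA on principal
    coordinates), and a synthetic OTU-table generator that provides ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    picante,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
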