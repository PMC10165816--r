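Package: endovirome
Title: Viral Catalog Construction and Spatial Ecology for Endolithic
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds filtered viral catalogs from predicted viral contigs and
    read-mapping coverage, and analyses their spatial ecology. Implements
    greedy 95% average-nucleotide-identity clustering of viral contigs into
    viral operational taxonomic units (vOTUs) with CD-HIT-equivalent
    semantics, breadth-of-coverage detection filtering with trimmed-mean
    abundance, BLAST-consensus phage host prediction with dual-database
    merging, simplified gene-sharing-network viral clusters with
    membership-based taxonomy, and permutation-based multivariate statistics
    (PERMANOVA, dispersion tests, Mantel distance-decay) on Hellinger
    distances. A synthetic-data generator plants known cluster structure,
    hosts, viral clusters and spatially autocorrelated communities so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
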