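Package: epsclust
Title: Mining and Comparative Analysis of Exopolysaccharide Biosynthesis Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects Wzy-dependent exopolysaccharide (EPS) biosynthesis gene
    clusters in annotated bacterial genomes by seed homology and genomic
    neighborhood expansion; assigns gene roles (epsA-E, glycosyltransferases,
    flippase wzx, polymerase wzy, precursor enzymes, transposases) and
    CAZy-style glycosyltransferase families by a two-method vote; classifies
    clusters as generic or non-generic, scores essential-gene completeness,
    GC deviation and transposase adjacency; builds two-level protein families
    by Markov clustering of an all-against-all similarity graph and computes
    family-diversity statistics; and compares clusters by hierarchical
    clustering of family presence/absence profiles and habitat-sharing
    partitions. Includes a synthetic-genome generator with a machine-readable
    truth table for end-to-end validation, and a transmembrane-topology
    predictor (hydropathy plus positive-inside rule) for flippase/polymerase
    candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    Matrix,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
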