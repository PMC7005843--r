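Package: ironScan
Title: Annotation of Iron Acquisition, Storage, Regulation, and Redox
    Cycling Genes in Genomes and Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens assembled genomes and metagenomes for iron-related
    gene repertoires. Predicted proteins are scored against a library of
    profile hidden Markov models with per-family calibrated bit-score
    cutoffs, supplemented by a pairwise homology fallback for families
    that lack reliable models. Per-gene hits are filtered by c-type
    heme-binding motif content and protein length where the family
    demands it, grouped into gene neighborhoods, and classified into
    twelve functional categories (iron transport, heme oxygenases and
    transport, siderophore synthesis and transport, regulation, iron
    oxidation and reduction, storage, magnetosome formation) by an
    operon-aware rule engine. Comparative outputs include per-sample
    count matrices normalized to predicted ORFs, row-scaled matrices
    for heatmaps, and Ward/Euclidean dendrograms with bootstrap
    support. Utilities for building family databases (homolog
    filtering, identity-based dereplication, bit-score cutoff
    selection) and a deterministic synthetic-fixture generator are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    pheatmap,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
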