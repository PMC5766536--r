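Package: ecrtminer
Title: Mining and Classification of Endogenous Caulimovirid
    Reverse-Transcriptase Loci in Plant Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for paleovirology surveys of plant
    genomes: a translated (six-frame) seed-and-extend homology search for
    endogenous caulimovirid reverse-transcriptase (ECRT) loci with
    Karlin-Altschul E-values, merging and flank extension of hit loci,
    two-pass classification against a dual-family reverse-transcriptase
    library (Caulimoviridae target vs Ty3/Gypsy outgroup), greedy
    centroid clustering and similarity-network delineation of operational
    taxonomic units, maximum-likelihood placement of locus sequences on a
    fixed reference tree under GTR+Gamma, and per-genome summaries
    (counts, densities per ungapped megabase, distribution matrices).
    A synthetic-data module plants mutationally decayed viral insertions
    and retroelement decoys into simulated genomes with ground-truth
    intervals so every stage is benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
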