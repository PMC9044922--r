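Package: gfam
Title: Gene-Family Classification and Heat-Stress Expression Analysis for
    Plant AP2/ERF Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide analysis of the plant
    AP2/ERF transcription-factor superfamily. Detects AP2 and B3 DNA-binding
    domains with bundled position-specific scoring profiles and classifies
    proteins into the ERF/DREB, AP2 and RAV families, with DREB/ERF
    sub-family assignment from the conserved residues at AP2-domain
    alignment positions 14 and 19 and WLG-motif variant cataloging.
    Computes protein biochemical properties (molecular weight, theoretical
    isoelectric point, GRAVY), calls segmental and tandem gene duplications
    from BLOSUM62 pairwise identity normalised by the longer sequence,
    builds neighbor-joining trees with bootstrap support, scans promoters
    for cis-regulatory elements from an editable catalog, analyses qPCR
    expression by the 2^-ddCt method with fold-change based trait
    categorisation of heat-tolerance candidate genes, and summarises
    root-depth heat-damage phenotypes. A synthetic-data generator with
    planted ground truth makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
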