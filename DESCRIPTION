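Package: strandtools
Title: Template-Strand Analysis of Single-Cell Strand-seq Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of directional single-cell Strand-seq sequencing
    libraries: per-chromosome template-strand inheritance calls (WW/WC/CC),
    library background estimation, read-depth ploidy calls, detection and
    fine localization of sister chromatid exchanges by circular binary
    segmentation with iterative refinement and a read-level walker,
    cross-library calling of recurrent rearrangements and reference-assembly
    misorientations, placement of orphan scaffolds onto built genomes by
    template-state concordance, and clustering/orientation/ordering of
    early-build assembly contigs into linkage groups.  Ships a Strand-seq
    simulator with a complete truth ledger so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
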