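Package: dgetag
Title: Digital Gene Expression Tag Profiling and Distance Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for NlaIII-anchored digital gene expression
    (DGE) tag libraries: raw-tag cleaning, CATG-anchored 21-mer mapping to a
    transcript and genome reference allowing one mismatch, transcripts-per-
    million quantification, Audic-Claverie exact tests with Benjamini-Hochberg
    false discovery rate control, sequencing-saturation and library-correlation
    quality control, contingency-table term enrichment, and MEGA-style distance
    phylogenetics (p-distance with pairwise deletion, neighbor-joining,
    bootstrap supports). Includes a synthetic-data generator that emulates
    multi-million-tag libraries with sequencing error, adaptor contamination,
    singleton noise and spiked fold changes so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ape,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
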