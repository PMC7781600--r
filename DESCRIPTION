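Package: trnascreen
Title: Family-Aware Analysis of Pooled CRISPR Screens Against Multi-Copy tRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled CRISPR screens that target multi-gene
    tRNA isodecoder families. Implements guide/target mismatch profiling at the
    family level (ON/OFF-target classification with configurable PAM handling),
    family-level tRNA-seq expression summaries, fold-changes and edited-read
    fractions, relative-fitness estimation from pooled-competition sgRNA counts,
    linear deconvolution of observed fitness into per-family contributions via
    an expression-reduction matrix, FACS sorted-bin enrichment and
    arrest-essentiality classification, and a seeded simulator that generates
    every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
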