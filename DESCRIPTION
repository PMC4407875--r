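Package: poolanchor
Title: Physical Map Anchoring from Sequenced Three-Dimensional BAC Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Anchors marker sequences to BAC clones and physical-map contigs
    from sequencing data of three-dimensionally pooled minimum-tiling-path
    (MTP) clones. Computes per-pool breadth of coverage of marker sequences
    from SAM alignments or coverage tables, calls positive pools at a
    covered-region threshold, and deconvolutes positive-pool signatures to
    clone addresses using the plate/row/column pooling arithmetic, the
    contig structure of the physical map, and Sulston fingerprint-overlap
    probabilities for relaxed-cutoff end-clone matching. Includes a
    stringency-sweep reanalysis, depth-saturation subsampling, anchoring
    quality control against an ordered gene ('zipper') or genetic map, and
    a full synthetic-experiment simulator with ground truth for recovery
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
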