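Package: polpause
Title: RNA Polymerase II Promoter-Proximal Pausing Analysis from ChIP-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying RNA polymerase II promoter-proximal pausing
    and elongation behaviour from ChIP-seq read intervals. Builds
    depth-normalized (optionally spike-in scaled) binned occupancy tracks from
    strand-extended reads, computes metagene profiles on a fixed-flank plus
    percent-scaled gene-body coordinate system, derives per-gene traveling
    ratios and 3' pausing indices with confidence tiering, classifies genes as
    active, bivalent or silent from histone-mark peak sets
    (H3K4me3/H3K79me2/H3K27me3), annotates peaks to genomic features, and
    integrates bound-gene sets with differential-expression tables. Includes a
    seeded synthetic-data generator that plants known promoter, gene-body,
    3'-end and background read components per gene so every stage can be
    validated against ground truth, and a pipeline driver that runs
    simulation through reporting end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
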