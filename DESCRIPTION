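Package: exchseq
Title: Quantitative Analysis of Dual-Tag Histone-Exchange Sensor ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying histone turnover from dual-tag (myc/HA)
    cleavage-sensor ChIP-seq experiments. Covers fragment import and filtering,
    5'-end shifting, binned coverage, depth normalization and replicate pooling;
    the exchange score (log2 myc/HA ratio with pseudocounts), mark enrichment,
    control-region normalization and turnover classification; region analytics
    (genome tiling, anchored and scaled-gene metaprofile matrices, covariate
    binning, trend smoothing); strand-aware exchange asymmetry around CTCF
    motifs; consensus repeat-library quantification with best-match multimapper
    assignment; replicate-level region-set contrasts with t-tests; and a
    seeded kinetic simulator of the sensor's myc/HA channels for validation.
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
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
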