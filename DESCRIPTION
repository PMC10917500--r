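Package: txinit
Title: Transcription Initiation Directionality at Promoters and
    Intergenic Accessible Regions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the directionality of RNA polymerase II
    transcription initiation at gene transcription start sites and at
    gene-proximal intergenic accessible regions (IARs) from coverage
    tracks of stranded nascent transcription and histone modifications.
    Provides bedtools-style interval arithmetic to derive IARs from
    accessible-chromatin intervals and a gene annotation, point-anchored
    and scaled-gene-body signal metaprofiles with standard error and 95
    percent confidence bands, k-means partitioning of multi-track region
    by bin signal matrices, an upstream/downstream skew test built on the
    Wilcoxon rank-sum statistic with Bonferroni correction, and a
    synthetic epigenome generator so the entire pipeline can be exercised
    and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
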