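Package: radmarker
Title: RAD-Seq Marker Discovery Between Two Varieties
Version: 0.1.0
Authors@R: person("radmarker", "developers", role = c("aut", "cre"),
    email = "radmarker@example.org")
Description: Discovery of SNP and InDel markers between two varieties from
    restriction-site associated DNA (RAD) sequencing data. Implements
    percentage-based FASTQ quality filtering with end trimming, in-silico
    restriction digestion for RAD tag yield assessment, parsing of samtools
    pileup text into per-position allele summaries, count-threshold SNP/InDel
    calling, two-sample (treat versus clean control) marker detection with
    coverage and spacing post-filters, gene-model based variant annotation
    (region categories and synonymous/nonsynonymous/stop effects), selection
    of markers flanking a target locus for marker-assisted selection, and a
    deterministic synthetic-data generator with truth-table evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    optparse,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
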