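Package: enhansr
Title: Screening for Enhancer-Associated Antisense RNAs in Stranded RNA-Seq
    Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting novel enhancer-associated
    antisense transcripts from strand-specific RNA-seq coverage. Provides
    readers and writers for BED, GTF, BedGraph and FASTA; RPKM and
    transcriptome-wide RPKM-percentile expression summaries; calibration of
    transcript-fragment merging thresholds from adjacent-exon percentile
    differences; a percentile-difference/gap merge rule for fragmented
    transcript assemblies; a rule-based screen for novel antisense transcripts
    co-expressed with active enhancer peaks; a sense isoform-shift statistic
    with a permutation test; open reading frame scanning with simple
    coding-potential heuristics; and a synthetic-data generator that plants
    condition-specific antisense loci, enhancer peaks and isoform shifts with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
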