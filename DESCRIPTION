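Package: isocompare
Title: Isoform-Level Comparison of Transcriptomes and Long Noncoding RNA
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares two expressed transcriptomes at gene and isoform
    resolution. Transcripts passing an RPKM threshold are labelled
    protein-coding, long noncoding (>200 nt) or short noncoding from
    coding-potential scores; samples are intersected by exon-chain
    identity; bifunctional genes (both a protein-coding and a long
    noncoding isoform) and category-switch genes are detected; novel
    long ncRNA structures are classified against annotation as intron
    retention, novel boundary/exon or exon skipping; conservation is
    summarised against per-base score tracks and predicted conserved
    elements for several clades; and long ncRNAs are screened for
    disease association via exact-and-unique microarray probe matching,
    two-group differential expression and a probe-gene correlation
    screen. Includes generators that synthesize every input with
    recorded ground truth.
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
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
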