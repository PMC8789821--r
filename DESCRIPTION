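Package: m6ascreen
Title: Design and Analysis of Base-Editor Screens for Single-Nucleotide m6A Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for adenine-base-editor (ABE) screens that convert
    single-nucleotide N6-methyladenosine (m6A) sites to A>G mutations.
    Enumerates editing-window/PAM-compatible sgRNAs for stranded m6A
    sites, designs CRISPR-STOP (C>T) control guides, annotates predicted
    edits with a region- and codon-level consequence classifier, counts
    guides from pooled-screen FASTQ reads, normalizes count matrices,
    and calls enriched guides in sorted populations with a moment-matched
    negative-binomial test built on a fitted mean-variance trend.
    Includes a synthetic-data generator producing toy genomes, guide
    libraries and ground-truth screens for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
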