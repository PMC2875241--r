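Package: ProbeRemap
Title: Remapping Expression Microarray Probes to Genes, Transcripts,
    Exons and Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact-match remapping of expression-microarray oligo probes
    against an annotated transcriptome. Probes are matched full length,
    with zero mismatches, to spliced transcript sequences, projected back
    onto genome coordinates (including multi-block placement of probes
    spanning exon-exon junctions), and classified by a fixed cascade into
    mRNA, noncoding RNA, intron-only (putative ncRNA) and unassigned
    categories, with gene-, transcript- and exon-level ambiguity flags.
    From the classified probes the package rebuilds probe-set definitions
    at gene, transcript, exon and ncRNA level (flat chip-definition
    files), computes coverage and efficiency statistics of the mapping,
    and summarizes probe-level intensity matrices to entity-level
    log2 signals. A seeded fixture generator produces synthetic genomes,
    annotations, ncRNA collections and probe sets with planted ground
    truth for every probe class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
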