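# In-code fixture builders shared across test files.

# annotation from a flat exon table (chrom/start/end/strand/gene_id/
# gene_name/transcript_id/exon_id/rank/biotype)
annotationFromTable <- function(tab) {
  .makeAnnotation(tab)
}

exonRow <- function(gene, tx, exon, start, end, rank, strand = "+",
                    biotype = "protein_coding", chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = gene, gene_name = gene, transcript_id = tx,
             exon_id = exon, rank = rank, biotype = biotype,
             stringsAsFactors = FALSE)
}

# single plus-strand gene, one transcript, two exons 101-150 / 201-260
twoExonAnnotation <- function(strand = "+") {
  annotationFromTable(rbind(
    exonRow("G1", "G1_T1", "G1_E1", 101, 150, if (strand == "+") 1 else 2,
            strand),
    exonRow("G1", "G1_T1", "G1_E2", 201, 260, if (strand == "+") 2 else 1,
            strand)))
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent reverse complement (no Biostrings), used as oracle
rcOracle <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, ""), function(x)
           paste(rev(x), collapse = ""), character(1)))
}

# brute-force full-length exact-match oracle via Biostrings::matchPattern
bruteForceHits <- function(probes, targets, searchRevcomp = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    s <- toupper(probes$sequence[i])
    if (grepl("[^ACGT]", s)) next
    for (nm in names(targets)) {
      subj <- Biostrings::DNAString(targets[[nm]])
      fwd <- Biostrings::start(
        Biostrings::matchPattern(s, subj, fixed = TRUE))
      for (o in fwd)
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = probes$probe_id[i], target_id = nm, offset = o,
          orientation = "forward", stringsAsFactors = FALSE)
      if (searchRevcomp) {
        rc <- Biostrings::start(
          Biostrings::matchPattern(rcOracle(s), subj, fixed = TRUE))
        for (o in rc)
          rows[[length(rows) + 1L]] <- data.frame(
            probe_id = probes$probe_id[i], target_id = nm, offset = o,
            orientation = "revcomp", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(probe_id = character(0), target_id = character(0),
                      offset = integer(0), orientation = character(0)))
  h <- do.call(rbind, rows)
  h <- h[order(h$probe_id, h$target_id, h$offset, h$orientation), ,
         drop = FALSE]
  rownames(h) <- NULL
  h
}

# a small but complete fixture for pipeline tests
smallFixture <- function(seed = 11) {
  simulateFixture(fixtureSpec(
    nGenes = 10L,
    probePlan = c(exonic_unique = 12L, junction = 8L,
                  multi_transcript = 8L, multi_gene = 6L, intronic = 8L,
                  ncrna_db = 6L, unmapped = 5L),
    seed = seed))
}
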