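test_that("toy GTF loads into a linked hierarchy with file coordinates preserved", {
  gtf <- system.file("extdata", "toy.gtf", package = "ProbeRemap")
  ann <- loadAnnotation(gtf)
  expect_s4_class(ann, "GenomeAnnotation")
  expect_equal(nGenes(ann), 2L)
  expect_equal(nTranscripts(ann), 3L)
  expect_equal(nExons(ann), 6L)
  # GTF is 1-based inclusive and so is the internal GRanges: identity
  ex <- exonRanges(ann)
  e1 <- ex[ex$exon_id == "GA_E1"][1]
  expect_equal(start(e1), 101L)
  expect_equal(end(e1), 150L)
  expect_equal(width(e1), 50L)
  g <- geneLoci(ann)
  expect_equal(g$biotype[g$gene_id == "GA"], "protein_coding")
  expect_equal(g$biotype[g$gene_id == "GB"], "noncoding")
  # locus span is the exon hull
  expect_equal(start(g[g$gene_id == "GA"]), 101L)
  expect_equal(end(g[g$gene_id == "GA"]), 450L)
})

test_that("a 4-transcript, 16-exon locus reports its counts", {
  # one locus with 16 distinct exons; 4 transcripts over subsets of them
  rows <- list()
  exonStarts <- 100 + (0:15) * 100
  for (t in 1:4) {
    use <- switch(t, 1:16, 1:12, c(1:4, 9:16), c(1:8, 13:16))
    for (i in seq_along(use)) {
      k <- use[i]
      rows[[length(rows) + 1L]] <- exonRow(
        "GM", paste0("GM_T", t), sprintf("GM_E%02d", k),
        exonStarts[k], exonStarts[k] + 49, i)
    }
  }
  ann <- annotationFromTable(do.call(rbind, rows))
  expect_equal(nGenes(ann), 1L)
  expect_equal(nTranscripts(ann), 4L)
  expect_equal(nExons(ann), 16L)
})

test_that("invalid hierarchies are rejected", {
  # overlapping exons within one transcript
  bad <- rbind(exonRow("G1", "G1_T1", "E1", 101, 160, 1),
               exonRow("G1", "G1_T1", "E2", 150, 200, 2))
  expect_error(annotationFromTable(bad), "overlapping")
  # non-consecutive ranks
  bad2 <- rbind(exonRow("G1", "G1_T1", "E1", 101, 150, 1),
                exonRow("G1", "G1_T1", "E2", 201, 250, 3))
  expect_error(annotationFromTable(bad2), "rank")
  # transcript feature with zero exons in a GTF
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "transcript", 1, 100, ".", "+", ".",
          'gene_id "G"; transcript_id "T0"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "t", "exon", 1, 100, ".", "+", ".",
          'gene_id "G"; transcript_id "T1"; exon_number "1"; gene_biotype "protein_coding";',
          sep = "\t")), gtf)
  expect_error(loadAnnotation(gtf), "zero exons")
  expect_error(loadAnnotation(tempfile()), "not found")
})

test_that("unknown biotypes fall back to noncoding with a warning", {
  expect_warning(bt <- .normalizeBiotype("weird_biotype"), "weird_biotype")
  expect_equal(bt, "noncoding")
  expect_silent(.normalizeBiotype(c("protein_coding", "lincRNA")))
})

test_that("spliced extraction concatenates exons in rank order", {
  genome <- c(chr1 = "ACGTNNNNTTGG")
  # exons covering bases 1-4 and 9-12
  annP <- annotationFromTable(rbind(
    exonRow("G1", "G1_T1", "E1", 1, 4, 1),
    exonRow("G1", "G1_T1", "E2", 9, 12, 2)))
  expect_equal(extractTranscriptSequence(annP, genome, "G1_T1"),
               "ACGTTTGG")
  # minus strand: reverse complement of the plus-strand splice, checked
  # against an independent per-base oracle
  annM <- annotationFromTable(rbind(
    exonRow("G1", "G1_T1", "E1", 9, 12, 1, strand = "-"),
    exonRow("G1", "G1_T1", "E2", 1, 4, 2, strand = "-")))
  expect_equal(extractTranscriptSequence(annM, genome, "G1_T1"),
               rcOracle("ACGTTTGG"))
  expect_equal(extractTranscriptSequence(annM, genome, "G1_T1"),
               "CCAAACGT")
  # single-exon transcript equals the genomic slice
  ann1 <- annotationFromTable(exonRow("G1", "G1_T1", "E1", 5, 8, 1))
  expect_equal(extractTranscriptSequence(ann1, genome, "G1_T1"), "NNNN")
  # exon beyond chromosome bounds
  annB <- annotationFromTable(exonRow("G1", "G1_T1", "E1", 5, 40, 1))
  expect_error(extractTranscriptSequence(annB, genome, "G1_T1"),
               "coordinate error")
})

test_that("pre-mRNA slice covers the hull and introns are the span minus exons", {
  set.seed(42)
  genome <- c(chr1 = randomSeq(400))
  ann <- annotationFromTable(rbind(
    exonRow("G1", "G1_T1", "E1", 101, 150, 1),
    exonRow("G1", "G1_T1", "E2", 201, 260, 2)))
  pre <- extractPremrnaSequence(ann, genome, "G1")
  expect_equal(pre, toupper(substr(genome[["chr1"]], 101, 260)))
  expect_equal(nchar(pre), 160L)
  # minus strand version is the reverse complement
  annM <- annotationFromTable(rbind(
    exonRow("G1", "G1_T1", "E1", 201, 260, 1, strand = "-"),
    exonRow("G1", "G1_T1", "E2", 101, 150, 2, strand = "-")))
  expect_equal(extractPremrnaSequence(annM, genome, "G1"), rcOracle(pre))
  # intron positions by set arithmetic: hull minus exon positions
  intr <- intronRanges(ann, "G1")
  got <- sort(unlist(Map(seq, start(intr), end(intr))))
  expected <- setdiff(101:260, c(101:150, 201:260))
  expect_equal(got, expected)
  expect_error(extractPremrnaSequence(ann, genome, "nope"), "unknown gene")
})

test_that("projection maps transcript intervals to genomic blocks", {
  ann <- annotationFromTable(rbind(
    exonRow("G1", "G1_T1", "E1", 101, 150, 1),
    exonRow("G1", "G1_T1", "E2", 201, 260, 2)))
  # 25 nt starting at transcript position 41 crosses the junction
  b <- projectToGenome(ann, "G1_T1", 41, 25)
  expect_equal(length(b), 2L)
  expect_equal(start(b), c(141L, 201L))
  expect_equal(end(b), c(150L, 215L))
  expect_equal(sum(width(b)), 25L)
  # fully inside exon 1: a single block
  b1 <- projectToGenome(ann, "G1_T1", 5, 20)
  expect_equal(length(b1), 1L)
  expect_equal(c(start(b1), end(b1)), c(105L, 124L))
  expect_error(projectToGenome(ann, "G1_T1", 100, 25), "coordinate error")
  expect_error(projectToGenome(ann, "G1_T1", 0, 5), "coordinate error")
})

test_that("projection round-trips for every base of fixture transcripts", {
  fx <- smallFixture(seed = 7)
  ann <- fx$annotation
  for (tid in transcriptInfo(ann)$transcript_id) {
    len <- transcriptInfo(ann)$spliced_length[
      transcriptInfo(ann)$transcript_id == tid]
    blocks <- projectToGenome(ann, tid, 1, len)
    expect_equal(sum(width(blocks)), len)
    pos <- unlist(Map(seq, start(blocks), end(blocks)))
    back <- genomeToTranscript(ann, tid, pos)
    expect_equal(sort(back), seq_len(len))
    # strand consistency: minus-strand splice equals revcomp of the
    # plus-strand concatenation of its genomic blocks
    sp <- extractTranscriptSequence(ann, fx$genome, tid)
    chr <- as.character(fx$genome[[1]])
    plus <- paste(substring(chr, start(blocks), end(blocks)),
                  collapse = "")
    ex <- exonRanges(ann)
    strand <- as.character(strand(ex[ex$transcript_id == tid][1]))
    expect_equal(sp, if (strand == "-") rcOracle(plus) else plus)
  }
})
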