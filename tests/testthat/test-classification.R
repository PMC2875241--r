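# a hand-built micro-universe: one coding gene (2 exons), one coding
# 4-transcript gene sharing its first exon, one noncoding gene; genome
# assembled so every region is distinct
microUniverse <- function(seed = 99) {
  set.seed(seed)
  chr <- randomSeq(3000)
  rows <- rbind(
    exonRow("G1", "G1_T1", "G1_E1", 101, 180, 1),
    exonRow("G1", "G1_T1", "G1_E2", 301, 380, 2))
  # gene 2: 4 transcripts all containing exon 1 (601-700); extra exons
  # 801-860 (T1,T2), 1001-1060 (T1,T3), 1201-1260 (T1,T4)
  rows <- rbind(rows,
    exonRow("G2", "G2_T1", "G2_E1", 601, 700, 1),
    exonRow("G2", "G2_T1", "G2_E2", 801, 860, 2),
    exonRow("G2", "G2_T1", "G2_E3", 1001, 1060, 3),
    exonRow("G2", "G2_T1", "G2_E4", 1201, 1260, 4),
    exonRow("G2", "G2_T2", "G2_E1", 601, 700, 1),
    exonRow("G2", "G2_T2", "G2_E2", 801, 860, 2),
    exonRow("G2", "G2_T3", "G2_E1", 601, 700, 1),
    exonRow("G2", "G2_T3", "G2_E3", 1001, 1060, 2),
    exonRow("G2", "G2_T4", "G2_E1", 601, 700, 1),
    exonRow("G2", "G2_T4", "G2_E4", 1201, 1260, 2))
  rows <- rbind(rows,
    exonRow("G3", "G3_T1", "G3_E1", 1501, 1600, 1,
            biotype = "noncoding"))
  list(genome = c(chr1 = chr), ann = annotationFromTable(rows), chr = chr)
}

test_that("a probe in one exon of one transcript is fully specific and green", {
  u <- microUniverse()
  probe <- data.frame(probe_id = "p1", probeset_id = "ps1",
                      sequence = substr(u$chr, 111, 135), array = "a")
  a <- classifyProbes(probe, u$ann, u$genome)
  expect_equal(a$category, "mRNA")
  expect_equal(a$genes, "G1")
  expect_equal(a$transcripts, "G1_T1")
  expect_equal(a$exons, "G1_E1")
  expect_false(a$junction)
  expect_true(a$gene_unique)
  expect_true(a$transcript_specific)
  expect_true(a$exon_specific)
  expect_equal(a$color, "green")
})

test_that("a probe hitting all four transcripts of a locus is not transcript-specific", {
  u <- microUniverse()
  probe <- data.frame(probe_id = "p1", probeset_id = "ps1",
                      sequence = substr(u$chr, 621, 645), array = "a")
  a <- classifyProbes(probe, u$ann, u$genome)
  expect_equal(a$category, "mRNA")
  expect_equal(a$transcripts, "G2_T1;G2_T2;G2_T3;G2_T4")
  expect_true(a$gene_unique)
  expect_false(a$transcript_specific)
  expect_true(a$exon_specific)   # one shared exon
  expect_equal(a$color, "yellow")
})

test_that("junction-spanning probes are flagged and carry no exon ids", {
  u <- microUniverse()
  # 10 nt from the end of G1_E1 + 15 nt from the start of G1_E2
  sp <- paste0(substr(u$chr, 171, 180), substr(u$chr, 301, 315))
  a <- classifyProbes(data.frame(probe_id = "p1", probeset_id = "ps",
                                 sequence = sp, array = "a"),
                      u$ann, u$genome)
  expect_equal(a$category, "mRNA")
  expect_true(a$junction)
  expect_equal(a$exons, "")
  expect_false(a$exon_specific)
  expect_equal(a$color, "green")  # still unique to one transcript
})

test_that("annotation noncoding hits and external ncRNA hits become ncRNA", {
  u <- microUniverse()
  set.seed(12)
  nc <- c(NCX = randomSeq(200))
  probes <- data.frame(
    probe_id = c("pAnn", "pDb"),
    probeset_id = "ps",
    sequence = c(substr(u$chr, 1521, 1545), substr(nc[[1]], 51, 75)),
    array = "a")
  a <- classifyProbes(probes, u$ann, u$genome, ncrna = nc)
  expect_equal(a$category, c("ncRNA", "ncRNA"))
  expect_equal(a$ncrna_targets, c("G3_T1", "NCX"))
  expect_equal(a$genes, c("G3", ""))       # annotation ncRNA keeps its locus
  expect_equal(a$color, c("black", "black"))
})

test_that("intron-only probes are classified as putative ncRNAs", {
  u <- microUniverse()
  # wholly inside the G1 intron (181..300)
  probe <- data.frame(probe_id = "p1", probeset_id = "ps",
                      sequence = substr(u$chr, 221, 245), array = "a")
  a <- classifyProbes(probe, u$ann, u$genome)
  expect_equal(a$category, "intronic_putative_ncRNA")
  expect_equal(a$genes, "G1")
  expect_equal(a$color, "black")
  # a probe straddling an exon boundary on the genome (not spliced) is
  # neither exonic nor wholly intronic: unassigned
  straddle <- data.frame(probe_id = "p2", probeset_id = "ps",
                         sequence = substr(u$chr, 171, 195), array = "a")
  a2 <- classifyProbes(straddle, u$ann, u$genome)
  expect_equal(a2$category, "NA")
  # without the intron stage the intronic probe is unassigned
  a3 <- classifyProbes(probe, u$ann, u$genome, intronStage = FALSE)
  expect_equal(a3$category, "NA")
  expect_error(classifyProbes(probe, u$ann, genome = NULL),
               "configuration error")
})

test_that("the cascade is monotone: later stages never change earlier assignments", {
  u <- microUniverse()
  probes <- data.frame(
    probe_id = c("pm", "pi", "pu"),
    probeset_id = "ps",
    sequence = c(substr(u$chr, 111, 135),   # mRNA
                 substr(u$chr, 221, 245),   # intronic
                 "ACGTACGTACGTACGTACGTACGTA"),
    array = "a")
  base <- classifyProbes(probes, u$ann, u$genome)
  # add an ncRNA collection that contains the mRNA probe's sequence:
  # the probe was already resolved at stage 1 and must not move
  nc <- c(DECOY = paste0(substr(u$chr, 101, 180), substr(u$chr, 221, 245)))
  with_nc <- classifyProbes(probes, u$ann, u$genome, ncrna = nc)
  expect_equal(with_nc[with_nc$probe_id == "pm", ],
               base[base$probe_id == "pm", ])
  # the intronic probe IS in the decoy, an earlier stage: it moves up
  expect_equal(with_nc$category[with_nc$probe_id == "pi"], "ncRNA")
})

test_that("multi-locus probes are red and multiple same-target hits collapse", {
  u <- microUniverse()
  # plant the same 25-mer in exons of G1 and G2
  chr <- u$chr
  substr(chr, 321, 345) <- substr(chr, 111, 135)
  probe <- data.frame(probe_id = "p1", probeset_id = "ps",
                      sequence = substr(chr, 111, 135), array = "a")
  a <- classifyProbes(probe, u$ann, c(chr1 = chr))
  expect_equal(a$category, "mRNA")
  expect_equal(a$genes, "G1")          # both copies are in G1 here
  expect_true(a$multi_hit)             # two occurrences in G1_T1
  # now a true two-locus probe
  chr2 <- u$chr
  substr(chr2, 621, 645) <- substr(chr2, 111, 135)
  probe2 <- data.frame(probe_id = "p1", probeset_id = "ps",
                       sequence = substr(chr2, 111, 135), array = "a")
  a2 <- classifyProbes(probe2, u$ann, c(chr1 = chr2))
  expect_equal(a2$genes, "G1;G2")
  expect_false(a2$gene_unique)
  expect_equal(a2$color, "red")
})

test_that("category partition counts and percentages are exact", {
  a <- .emptyAssignments(sprintf("p%02d", 1:10))
  a$category <- c(rep("mRNA", 7), "ncRNA", "intronic_putative_ncRNA", "NA")
  pc <- partitionCounts(a)
  expect_equal(pc$n, c(7L, 2L, 1L))
  expect_equal(pc$pct, c(70, 20, 10))
  expect_equal(sum(pc$n), nrow(a))
  allNA <- .emptyAssignments(c("p1", "p2"))
  pcNA <- partitionCounts(allNA)
  expect_equal(pcNA$pct, c(0, 0, 100))
  expect_error(partitionCounts(allNA[0, ]), "no probe")
})

test_that("the color code follows the documented convention", {
  a <- .emptyAssignments(sprintf("p%d", 1:4))
  a$category <- c("mRNA", "mRNA", "mRNA", "NA")
  a$gene_unique <- c(TRUE, TRUE, FALSE, FALSE)
  a$transcript_specific <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(assignColor(a), c("green", "yellow", "red", "black"))
})
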