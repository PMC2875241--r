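mkAssign <- function(ids, category, genes, transcripts = "", exons = "",
                     ncrna = "", junction = FALSE, gene_unique = FALSE) {
  a <- .emptyAssignments(ids)
  a$category <- category
  a$genes <- genes
  a$transcripts <- transcripts
  a$exons <- exons
  a$ncrna_targets <- ncrna
  a$junction <- junction
  a$gene_unique <- gene_unique
  a$color <- assignColor(a)
  a
}

test_that("gene-level sets exclude ambiguous probes and honor the threshold", {
  a <- mkAssign(c("p1", "p2", "p3", "p4"), "mRNA",
                genes = c("G", "G", "G", "G;H"),
                transcripts = c("T1", "T1", "T2", "T1;H1"),
                gene_unique = c(TRUE, TRUE, TRUE, FALSE))
  s <- buildSets(a, "gene")
  expect_equal(s$entity_id, "G")
  expect_equal(s$probe_ids[[1]], c("p1", "p2", "p3"))
  expect_equal(s$n_probes, 3L)
  # min_probes threshold drops the set
  s4 <- buildSets(a, "gene", minProbes = 4)
  expect_equal(nrow(s4), 0L)
  expect_error(buildSets(a, "bogus"), "arg")
})

test_that("a probe appears in every transcript set of its unique gene", {
  a <- mkAssign("p1", "mRNA", genes = "G", transcripts = "T1;T2;T3",
                gene_unique = TRUE)
  s <- buildSets(a, "transcript")
  expect_equal(s$entity_id, c("T1", "T2", "T3"))
  expect_true(all(vapply(s$probe_ids, identical, logical(1), "p1")))
})

test_that("exon sets take only non-junction exon hits; ncRNA sets pool intronic probes", {
  a <- mkAssign(c("pj", "pe", "pn", "pi"),
                category = c("mRNA", "mRNA", "ncRNA",
                             "intronic_putative_ncRNA"),
                genes = c("G", "G", "", "H"),
                transcripts = c("T1", "T1", "", ""),
                exons = c("", "E1", "", ""),
                ncrna = c("", "", "NC1", ""),
                junction = c(TRUE, FALSE, FALSE, FALSE),
                gene_unique = c(TRUE, TRUE, FALSE, FALSE))
  sx <- buildSets(a, "exon")
  expect_equal(sx$entity_id, "E1")
  expect_equal(sx$probe_ids[[1]], "pe")
  sn <- buildSets(a, "ncRNA")
  expect_equal(sn$entity_id, c("H", "NC1"))
  expect_equal(unlist(sn$probe_ids), c("pi", "pn"))
})

test_that("set membership on a fixture equals the planted truth", {
  fx <- smallFixture(seed = 23)
  a <- classifyProbes(fx$probes, fx$annotation, fx$genome, fx$ncrna)
  s <- buildSets(a, "gene")
  # planted truth: gene-unique mRNA probes grouped by their single gene
  tr <- fx$truth
  uniq <- tr[tr$category == "mRNA" & as.logical(tr$gene_unique), ]
  want <- split(uniq$probe_id, uniq$genes)
  want <- lapply(want, sort)
  got <- s$probe_ids
  names(got) <- s$entity_id
  expect_equal(got[order(names(got))], want[order(names(want))],
               ignore_attr = TRUE)
  expect_equal(sort(s$entity_id), sort(names(want)))
})

test_that("mapping files are disjoint, complete and byte-deterministic", {
  fx <- smallFixture(seed = 23)
  a <- classifyProbes(fx$probes, fx$annotation, fx$genome, fx$ncrna)
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  m1 <- writeMappingFiles(a, fx$probes, d1)
  m2 <- writeMappingFiles(a, fx$probes, d2)
  expect_setequal(names(m1),
                  c("probes2genes", "probes2transcripts",
                    "probesets2genes", "ambigprobes2genes",
                    paste0("sets_", c("gene", "transcript", "exon",
                                      "ncRNA"))))
  for (nm in names(m1))
    expect_identical(readLines(m1[[nm]]), readLines(m2[[nm]]))
  p2g <- .readTsv(m1[["probes2genes"]])
  amb <- .readTsv(m1[["ambigprobes2genes"]])
  # unambiguous and ambiguous gene files partition the mRNA probes
  expect_length(intersect(p2g$probe_id, amb$probe_id), 0)
  expect_setequal(c(p2g$probe_id, amb$probe_id),
                  a$probe_id[a$category == "mRNA"])
  # ambiguous rows = planted multi-gene probes
  expect_equal(sort(amb$probe_id),
               sort(fx$truth$probe_id[fx$truth$class == "multi_gene"]))
  # every id written exists in the inputs
  expect_true(all(p2g$probe_id %in% fx$probes$probe_id))
  expect_true(all(p2g$gene_id %in% geneLoci(fx$annotation)$gene_id))
})

test_that("probesets2genes requires unanimity of its members", {
  a <- mkAssign(c("p1", "p2", "p3", "p4"), "mRNA",
                genes = c("G", "G", "H", "G"),
                transcripts = c("T1", "T1", "H1", "T1"),
                gene_unique = TRUE)
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       probeset_id = c("psA", "psA", "psA", "psB"),
                       sequence = "ACGT", array = "a")
  d <- tempfile()
  expect_message(m <- writeMappingFiles(a, probes, d), "discordant")
  ps <- .readTsv(m[["probesets2genes"]])
  # psA split across G and H: dropped; psB unanimous on G: kept
  expect_equal(ps$probeset_id, "psB")
  expect_equal(ps$gene_id, "G")
})
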