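#' Specification for a synthetic fixture
#'
#' Parameters of the synthetic genome / annotation / probe generator.
#' The defaults describe a desk-scale study: a 20-gene locus set with a
#' noncoding fraction, multi-transcript loci built by internal exon
#' skipping, short introns for fast tests, 25-mer probes, and a probe
#' plan of about 200 probes spanning all seven planted classes
#' (\code{exonic_unique}, \code{junction}, \code{multi_transcript},
#' \code{multi_gene}, \code{intronic}, \code{ncrna_db},
#' \code{unmapped}). The seed fully determines every output.
#'
#' @param nGenes number of gene loci
#' @param transcriptsPerGene range (lo, hi) of transcripts for
#'   multi-transcript loci
#' @param exonsPerTranscript range of exons per transcript
#' @param exonLength,intronLength ranges in nt
#' @param fracNoncoding fraction of loci given a noncoding biotype
#' @param probePlan named integer vector of probe counts per planted
#'   class
#' @param probeLength probe length in nt
#' @param nNcrnaSeqs,ncrnaLength external ncRNA collection size and
#'   sequence length
#' @param seed RNG seed
#' @return an object of class \code{FixtureSpec}
#' @seealso \code{\link{simulateFixture}}
#' @export
fixtureSpec <- function(nGenes = 20L,
                        transcriptsPerGene = c(2L, 4L),
                        exonsPerTranscript = c(4L, 6L),
                        exonLength = c(80L, 120L),
                        intronLength = c(60L, 200L),
                        fracNoncoding = 0.15,
                        probePlan = c(exonic_unique = 50L, junction = 30L,
                                      multi_transcript = 35L,
                                      multi_gene = 16L, intronic = 25L,
                                      ncrna_db = 24L, unmapped = 20L),
                        probeLength = 25L,
                        nNcrnaSeqs = 6L, ncrnaLength = 400L,
                        seed = 1L) {
  classes <- c("exonic_unique", "junction", "multi_transcript",
               "multi_gene", "intronic", "ncrna_db", "unmapped")
  plan <- structure(integer(length(classes)), names = classes)
  plan[names(probePlan)] <- as.integer(probePlan)
  if (any(plan < 0) || nGenes < 1 || fracNoncoding < 0 || fracNoncoding > 1)
    stop("invalid fixture specification")
  if (probeLength < 8)
    stop("probe length must be >= 8")
  spec <- list(nGenes = as.integer(nGenes),
               transcriptsPerGene = as.integer(transcriptsPerGene),
               exonsPerTranscript = as.integer(exonsPerTranscript),
               exonLength = as.integer(exonLength),
               intronLength = as.integer(intronLength),
               fracNoncoding = fracNoncoding,
               probePlan = plan,
               probeLength = as.integer(probeLength),
               nNcrnaSeqs = as.integer(nNcrnaSeqs),
               ncrnaLength = as.integer(ncrnaLength),
               seed = as.integer(seed))
  class(spec) <- "FixtureSpec"
  spec
}

.sampleIn <- function(rng, n = 1L) {
  if (rng[1] >= rng[2]) rep(rng[1], n)
  else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

.rcChar <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x)
           paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

# interior slot start offsets (1-based local coords) within a feature of
# length len, keeping a 5 nt margin at both ends
.slotStarts <- function(len, L) {
  last <- len - 5L - L + 1L
  if (last < 6L) integer(0) else seq(6L, last, by = L + 5L)
}

#' Generate a complete synthetic fixture with planted ground truth
#'
#' Builds a random genome, a gene/transcript/exon annotation, an
#' external ncRNA collection and a probe set in which every probe
#' belongs, by construction, to one of seven planted classes:
#' exon-interior probes unique to one transcript of one locus, probes
#' spanning an exon-exon junction, probes in an exon shared by several
#' transcripts, probes duplicated into the exons of two loci
#' (multi-gene, ambiguous), intron-only probes, probes from the external
#' ncRNA collection, and unmapped probes (random sequences rejection-
#' sampled until absent from every mapping target in both orientations).
#' Multi-transcript loci are built by skipping one internal exon per
#' alternative transcript; multi-gene probes are created by copying the
#' probe's genomic sequence into an exon of a second dedicated locus.
#'
#' The truth table lists the expected category, hit sets and ambiguity
#' flags for every probe, in the same encoding as
#' \code{\link{classifyProbes}} output, so pipeline-versus-truth
#' agreement can be checked field by field.
#'
#' @param spec a \code{\link{fixtureSpec}}
#' @param dir if non-NULL, write \code{genome.fa}, \code{annotation.gtf},
#'   \code{ncrna.fa}, \code{probes.tsv} and \code{truth.tsv} there
#' @return (invisibly) a list with elements \code{genome}
#'   (DNAStringSet), \code{annotation} (\linkS4class{GenomeAnnotation}),
#'   \code{ncrna} (named character), \code{probes}, \code{truth}
#'   (data.frames) and \code{files} (manifest, when \code{dir} is given)
#' @export
simulateFixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  plan <- spec$probePlan
  L <- spec$probeLength

  if (plan["junction"] > 0 && max(spec$exonsPerTranscript) < 2)
    stop("generation error: junction probes require multi-exon transcripts")
  if (plan["intronic"] > 0 && max(spec$exonsPerTranscript) < 2)
    stop("generation error: intronic probes require multi-exon loci")
  if (plan["multi_transcript"] > 0 && max(spec$transcriptsPerGene) < 2)
    stop("generation error: multi_transcript probes require multi-transcript loci")

  # ---- gene roles ----------------------------------------------------
  nNc <- round(spec$fracNoncoding * spec$nGenes)
  nCoding <- spec$nGenes - nNc
  nPairs <- if (plan["multi_gene"] > 0) ceiling(plan["multi_gene"] / 12) else 0L
  nMulti <- if (plan["multi_transcript"] > 0)
    max(1L, ceiling(plan["multi_transcript"] / 6)) else 0L
  nUni <- nCoding - 2L * nPairs - nMulti
  needUni <- sum(plan[c("exonic_unique", "junction")]) > 0
  if (nUni < as.integer(needUni))
    stop("generation error: not enough coding loci for the probe plan (",
         nCoding, " coding loci; need ", 2 * nPairs, " multi-gene + ",
         nMulti, " multi-transcript + >=", as.integer(needUni), " single-transcript)")
  roles <- c(rep("mg", 2L * nPairs), rep("multi", nMulti),
             rep("uni", nUni), rep("noncoding", nNc))

  # ---- gene structures ----------------------------------------------
  maxE <- max(spec$exonsPerTranscript)
  genes <- vector("list", spec$nGenes)
  cursor <- 1L
  for (g in seq_len(spec$nGenes)) {
    role <- roles[g]
    nT <- switch(role,
                 multi = .sampleIn(pmax(spec$transcriptsPerGene, c(2L, 2L))),
                 1L)
    nE <- switch(role,
                 mg = max(maxE, 4L),
                 multi = max(maxE, nT + 2L),
                 .sampleIn(spec$exonsPerTranscript))
    exLen <- switch(role,
                    mg = rep(max(spec$exonLength), nE),
                    .sampleIn(spec$exonLength, nE))
    inLen <- if (nE > 1) .sampleIn(spec$intronLength, nE - 1L) else integer(0)
    strand <- sample(c("+", "-"), 1L)
    span <- sum(exLen) + sum(inLen)
    gStart <- cursor + .sampleIn(c(150L, 300L))
    gEnd <- gStart + span - 1L
    cursor <- gEnd
    # transcript-axis coordinates (1 = 5' end of the locus)
    axStart <- cumsum(c(1L, utils::head(exLen + c(inLen, 0L), -1L)))
    axEnd <- axStart + exLen - 1L
    # genomic coordinates of exon rank k
    if (strand == "+") {
      eStart <- gStart + axStart - 1L
      eEnd <- gStart + axEnd - 1L
    } else {
      eEnd <- gEnd - axStart + 1L
      eStart <- gEnd - axEnd + 1L
    }
    # transcript 1 = all exons; transcript t drops internal rank t
    txExons <- list(seq_len(nE))
    if (nT > 1)
      for (t in 2:nT) txExons[[t]] <- setdiff(seq_len(nE), t)
    gid <- sprintf("G%03d", g)
    genes[[g]] <- list(gene_id = gid, role = role, strand = strand,
                       biotype = if (role == "noncoding") "noncoding"
                                 else "protein_coding",
                       gStart = gStart, gEnd = gEnd,
                       nE = nE, nT = nT, exLen = exLen, inLen = inLen,
                       axStart = axStart, axEnd = axEnd,
                       eStart = eStart, eEnd = eEnd,
                       exon_ids = sprintf("%s_E%02d", gid, seq_len(nE)),
                       tx_ids = sprintf("%s_T%d", gid, seq_len(nT)),
                       txExons = txExons)
  }
  chromLen <- cursor + 200L

  # ---- genome sequence ----------------------------------------------
  chars <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)

  # slot bookkeeping: per gene, per exon / intron, remaining slot starts
  exSlots <- lapply(genes, function(gn)
    lapply(gn$exLen, .slotStarts, L = L))
  inSlots <- lapply(genes, function(gn)
    lapply(gn$inLen, .slotStarts, L = L))

  takeExonSlot <- function(g, k) {
    s <- exSlots[[g]][[k]]
    if (length(s) == 0) return(NULL)
    exSlots[[g]][[k]] <<- s[-1]
    s[1]
  }

  # genomic interval of a local exon offset (transcript orientation)
  slotGenomic <- function(gn, k, o) {
    if (gn$strand == "+") {
      st <- gn$eStart[k] + o - 1L
      c(st, st + L - 1L)
    } else {
      en <- gn$eEnd[k] - o + 1L
      c(en - L + 1L, en)
    }
  }

  # ---- multi-gene duplications (modify the genome first) -------------
  mgSites <- list()
  if (plan["multi_gene"] > 0) {
    pairIdx <- matrix(seq_len(2L * nPairs), ncol = 2, byrow = TRUE)
    for (j in seq_len(plan["multi_gene"])) {
      p <- ((j - 1L) %% nPairs) + 1L
      gA <- pairIdx[p, 1]; gB <- pairIdx[p, 2]
      src <- tgt <- NULL
      for (k in seq_len(genes[[gA]]$nE))
        if (!is.null(o <- takeExonSlot(gA, k))) { src <- c(k, o); break }
      for (k in seq_len(genes[[gB]]$nE))
        if (!is.null(o <- takeExonSlot(gB, k))) { tgt <- c(k, o); break }
      if (is.null(src) || is.null(tgt))
        stop("generation error: insufficient exon slots for multi_gene probes")
      gi <- slotGenomic(genes[[gA]], src[1], src[2])
      ti <- slotGenomic(genes[[gB]], tgt[1], tgt[2])
      chars[ti[1]:ti[2]] <- chars[gi[1]:gi[2]]
      mgSites[[j]] <- list(gA = gA, kA = src[1], oA = src[2],
                           gB = gB, kB = tgt[1], oB = tgt[2])
    }
  }

  genomeStr <- paste(chars, collapse = "")

  # ---- derived sequences (independent splice arithmetic) -------------
  premrna <- function(gn) {
    s <- substr(genomeStr, gn$gStart, gn$gEnd)
    if (gn$strand == "-") .rcChar(s) else s
  }
  spliced <- function(gn, t) {
    ranks <- gn$txExons[[t]]
    pre <- premrna(gn)
    paste(vapply(ranks, function(k)
      substr(pre, gn$axStart[k], gn$axEnd[k]), character(1)),
      collapse = "")
  }
  splicedCache <- lapply(genes, function(gn)
    lapply(seq_len(gn$nT), function(t) spliced(gn, t)))

  ncrna <- NULL
  if (spec$nNcrnaSeqs > 0) {
    ncrna <- vapply(seq_len(spec$nNcrnaSeqs), function(i)
      paste(sample(c("A", "C", "G", "T"), spec$ncrnaLength, replace = TRUE),
            collapse = ""), character(1))
    names(ncrna) <- sprintf("NC%03d", seq_len(spec$nNcrnaSeqs))
  }

  # ---- probes and truth ----------------------------------------------
  truthRow <- function(probe_id, class, category, genes = "",
                       transcripts = "", exons = "", ncrna_targets = "",
                       junction = FALSE, gene_unique = FALSE,
                       transcript_specific = FALSE, exon_specific = FALSE) {
    color <- if (category != "mRNA") "black"
             else if (!gene_unique) "red"
             else if (transcript_specific) "green" else "yellow"
    data.frame(probe_id = probe_id, class = class, category = category,
               genes = genes, transcripts = transcripts, exons = exons,
               ncrna_targets = ncrna_targets, junction = junction,
               gene_unique = gene_unique,
               transcript_specific = transcript_specific,
               exon_specific = exon_specific, color = color,
               stringsAsFactors = FALSE)
  }

  probeRows <- list(); truthRows <- list()
  pcount <- 0L
  addProbe <- function(sequence, probeset, array, truth) {
    pcount <<- pcount + 1L
    pid <- sprintf("P%04d", pcount)
    probeRows[[pcount]] <<- data.frame(probe_id = pid,
                                       probeset_id = probeset,
                                       sequence = sequence,
                                       array = array,
                                       stringsAsFactors = FALSE)
    truth$probe_id <- pid
    truthRows[[pcount]] <<- truth
  }

  uniIdx <- which(roles == "uni")
  multiIdx <- which(roles == "multi")

  # exonic_unique: interior of an exon of a single-transcript locus
  if (plan["exonic_unique"] > 0) {
    cands <- do.call(rbind, lapply(uniIdx, function(g)
      expand.grid(g = g, k = seq_len(genes[[g]]$nE))))
    ci <- 0L
    for (j in seq_len(plan["exonic_unique"])) {
      slot <- NULL
      while (is.null(slot)) {
        ci <- ci + 1L
        if (ci > nrow(cands) * 10L)
          stop("generation error: insufficient exon slots for exonic_unique probes")
        r <- cands[((ci - 1L) %% nrow(cands)) + 1L, ]
        o <- takeExonSlot(r$g, r$k)
        if (!is.null(o)) slot <- list(g = r$g, k = r$k, o = o)
      }
      gn <- genes[[slot$g]]
      splicedPos <- sum(gn$exLen[seq_len(slot$k - 1L)]) + slot$o
      seqc <- substr(splicedCache[[slot$g]][[1]], splicedPos,
                     splicedPos + L - 1L)
      addProbe(seqc, paste0("ps_", gn$gene_id), "simarray",
               truthRow(NA, "exonic_unique", "mRNA",
                        genes = gn$gene_id, transcripts = gn$tx_ids[1],
                        exons = gn$exon_ids[slot$k],
                        gene_unique = TRUE, transcript_specific = TRUE,
                        exon_specific = TRUE))
    }
  }

  # junction: spans the boundary between consecutive exons of a
  # single-transcript locus
  if (plan["junction"] > 0) {
    avals <- c(8L, 12L, 16L)
    avals <- avals[avals <= L - 8L]
    cands <- do.call(rbind, lapply(uniIdx, function(g) {
      gn <- genes[[g]]
      if (gn$nE < 2) return(NULL)
      expand.grid(g = g, jn = seq_len(gn$nE - 1L), a = avals)
    }))
    if (is.null(cands) || nrow(cands) < plan["junction"])
      stop("generation error: insufficient junction slots (need ",
           plan["junction"], ", have ",
           if (is.null(cands)) 0 else nrow(cands), ")")
    for (j in seq_len(plan["junction"])) {
      r <- cands[j, ]
      gn <- genes[[r$g]]
      splicedPos <- sum(gn$exLen[seq_len(r$jn)]) - r$a + 1L
      seqc <- substr(splicedCache[[r$g]][[1]], splicedPos,
                     splicedPos + L - 1L)
      addProbe(seqc, paste0("ps_", gn$gene_id), "simarray",
               truthRow(NA, "junction", "mRNA",
                        genes = gn$gene_id, transcripts = gn$tx_ids[1],
                        junction = TRUE, gene_unique = TRUE,
                        transcript_specific = TRUE))
    }
  }

  # multi_transcript: interior of an exon present in >=2 transcripts
  if (plan["multi_transcript"] > 0) {
    cands <- do.call(rbind, lapply(multiIdx, function(g) {
      gn <- genes[[g]]
      memb <- vapply(seq_len(gn$nE), function(k)
        sum(vapply(gn$txExons, function(e) k %in% e, logical(1))),
        integer(1))
      ks <- which(memb >= 2L)
      if (length(ks) == 0) return(NULL)
      expand.grid(g = g, k = ks)
    }))
    ci <- 0L
    for (j in seq_len(plan["multi_transcript"])) {
      slot <- NULL
      while (is.null(slot)) {
        ci <- ci + 1L
        if (is.null(cands) || ci > nrow(cands) * 10L)
          stop("generation error: insufficient shared-exon slots for multi_transcript probes")
        r <- cands[((ci - 1L) %% nrow(cands)) + 1L, ]
        o <- takeExonSlot(r$g, r$k)
        if (!is.null(o)) slot <- list(g = r$g, k = r$k, o = o)
      }
      gn <- genes[[slot$g]]
      members <- which(vapply(gn$txExons, function(e) slot$k %in% e,
                              logical(1)))
      splicedPos <- sum(gn$exLen[seq_len(slot$k - 1L)]) + slot$o
      seqc <- substr(splicedCache[[slot$g]][[1]], splicedPos,
                     splicedPos + L - 1L)
      addProbe(seqc, paste0("ps_", gn$gene_id), "simarray",
               truthRow(NA, "multi_transcript", "mRNA",
                        genes = gn$gene_id,
                        transcripts = .joinIds(gn$tx_ids[members]),
                        exons = gn$exon_ids[slot$k],
                        gene_unique = TRUE,
                        transcript_specific = length(members) == 1L,
                        exon_specific = TRUE))
    }
  }

  # multi_gene: the duplicated sites prepared above
  for (j in seq_along(mgSites)) {
    s <- mgSites[[j]]
    gA <- genes[[s$gA]]; gB <- genes[[s$gB]]
    splicedPos <- sum(gA$exLen[seq_len(s$kA - 1L)]) + s$oA
    seqc <- substr(splicedCache[[s$gA]][[1]], splicedPos, splicedPos + L - 1L)
    addProbe(seqc, sprintf("ps_mg%02d", ((j - 1L) %% nPairs) + 1L),
             "simarray",
             truthRow(NA, "multi_gene", "mRNA",
                      genes = .joinIds(c(gA$gene_id, gB$gene_id)),
                      transcripts = .joinIds(c(gA$tx_ids[1], gB$tx_ids[1])),
                      exons = .joinIds(c(gA$exon_ids[s$kA],
                                         gB$exon_ids[s$kB]))))
  }

  # intronic: interior of an intron, outside every transcript's exons
  if (plan["intronic"] > 0) {
    hostIdx <- c(uniIdx, multiIdx)
    cands <- do.call(rbind, lapply(hostIdx, function(g) {
      gn <- genes[[g]]
      if (gn$nE < 2) return(NULL)
      expand.grid(g = g, i = seq_len(gn$nE - 1L))
    }))
    ci <- 0L
    for (j in seq_len(plan["intronic"])) {
      slot <- NULL
      while (is.null(slot)) {
        ci <- ci + 1L
        if (is.null(cands) || ci > nrow(cands) * 10L)
          stop("generation error: insufficient intron slots for intronic probes")
        r <- cands[((ci - 1L) %% nrow(cands)) + 1L, ]
        s <- inSlots[[r$g]][[r$i]]
        if (length(s)) {
          inSlots[[r$g]][[r$i]] <- s[-1]
          slot <- list(g = r$g, i = r$i, o = s[1])
        }
      }
      gn <- genes[[slot$g]]
      axPos <- gn$axEnd[slot$i] + slot$o
      seqc <- substr(premrna(gn), axPos, axPos + L - 1L)
      addProbe(seqc, paste0("ps_int_", gn$gene_id), "simarray",
               truthRow(NA, "intronic", "intronic_putative_ncRNA",
                        genes = gn$gene_id))
    }
  }

  # ncrna_db: interiors of the external collection
  if (plan["ncrna_db"] > 0) {
    if (is.null(ncrna))
      stop("generation error: ncrna_db probes require nNcrnaSeqs > 0")
    ncSlots <- lapply(ncrna, function(s) .slotStarts(nchar(s), L))
    ci <- 0L
    for (j in seq_len(plan["ncrna_db"])) {
      slot <- NULL
      while (is.null(slot)) {
        ci <- ci + 1L
        if (ci > length(ncrna) * 100L)
          stop("generation error: insufficient slots for ncrna_db probes")
        i <- ((ci - 1L) %% length(ncrna)) + 1L
        s <- ncSlots[[i]]
        if (length(s)) {
          ncSlots[[i]] <- s[-1]
          slot <- list(i = i, o = s[1])
        }
      }
      nm <- names(ncrna)[slot$i]
      seqc <- substr(ncrna[[slot$i]], slot$o, slot$o + L - 1L)
      addProbe(seqc, paste0("ps_nc_", nm), "simarray",
               truthRow(NA, "ncrna_db", "ncRNA", ncrna_targets = nm))
    }
  }

  # all mapping targets, both orientations, for rejection sampling
  allTargets <- c(unlist(splicedCache), unname(ncrna),
                  vapply(genes, premrna, character(1)))
  targetCat <- paste(c(allTargets, .rcChar(allTargets)), collapse = "|")

  # verify by construction: intron-only probes must be absent from the
  # spliced and external targets
  splicedCat <- paste(c(unlist(splicedCache), unname(ncrna),
                        .rcChar(c(unlist(splicedCache), unname(ncrna)))),
                      collapse = "|")
  for (i in seq_along(truthRows)) {
    if (truthRows[[i]]$class == "intronic" &&
        grepl(probeRows[[i]]$sequence, splicedCat, fixed = TRUE))
      stop("generation error: planted intronic probe collides with a spliced target")
  }

  # unmapped: rejection-sampled against every target in both orientations
  if (plan["unmapped"] > 0) {
    for (j in seq_len(plan["unmapped"])) {
      repeat {
        seqc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
        if (!grepl(seqc, targetCat, fixed = TRUE)) break
      }
      addProbe(seqc, "ps_na", "simarray",
               truthRow(NA, "unmapped", "NA"))
    }
  }

  probes <- do.call(rbind, probeRows)
  truth <- do.call(rbind, truthRows)
  if (is.null(probes))
    stop("generation error: empty probe plan")
  rownames(probes) <- rownames(truth) <- NULL

  # ---- annotation object ---------------------------------------------
  annTab <- do.call(rbind, lapply(genes, function(gn) {
    do.call(rbind, lapply(seq_len(gn$nT), function(t) {
      ranks <- gn$txExons[[t]]
      data.frame(chrom = "chr1",
                 start = gn$eStart[ranks], end = gn$eEnd[ranks],
                 strand = gn$strand, gene_id = gn$gene_id,
                 gene_name = gn$gene_id,
                 transcript_id = gn$tx_ids[t],
                 exon_id = gn$exon_ids[ranks],
                 rank = seq_along(ranks),
                 biotype = gn$biotype, stringsAsFactors = FALSE)
    }))
  }))
  annotation <- .makeAnnotation(annTab)
  genome <- DNAStringSet(c(chr1 = genomeStr))

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create fixture directory: ", dir)
    files <- c(genome = file.path(dir, "genome.fa"),
               annotation = file.path(dir, "annotation.gtf"),
               ncrna = file.path(dir, "ncrna.fa"),
               probes = file.path(dir, "probes.tsv"),
               truth = file.path(dir, "truth.tsv"))
    .writeFasta(c(chr1 = genomeStr), files["genome"])
    .writeGtf(annTab, files["annotation"])
    if (!is.null(ncrna)) .writeFasta(ncrna, files["ncrna"])
    else writeLines(character(0), files["ncrna"])
    .writeTsv(probes, files["probes"])
    .writeTsv(truth, files["truth"])
  }
  invisible(list(spec = spec, genome = genome, annotation = annotation,
                 ncrna = ncrna, probes = probes, truth = truth,
                 files = files))
}

.writeFasta <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

.writeGtf <- function(annTab, path) {
  attr1 <- function(gid)
    sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
            gid$gene_id, gid$gene_name, gid$biotype)
  lines <- character(0)
  for (gid in unique(annTab$gene_id)) {
    gt <- annTab[annTab$gene_id == gid, , drop = FALSE]
    lines <- c(lines, paste("chr1", "sim", "gene",
                            min(gt$start), max(gt$end), ".",
                            gt$strand[1], ".", attr1(gt[1, ]),
                            sep = "\t"))
    for (tid in unique(gt$transcript_id)) {
      tt <- gt[gt$transcript_id == tid, , drop = FALSE]
      tattr <- sprintf('%s transcript_id "%s";', attr1(tt[1, ]), tid)
      lines <- c(lines, paste("chr1", "sim", "transcript",
                              min(tt$start), max(tt$end), ".",
                              tt$strand[1], ".", tattr, sep = "\t"))
      for (i in seq_len(nrow(tt))) {
        eattr <- sprintf('%s exon_number "%d"; exon_id "%s";',
                         tattr, tt$rank[i], tt$exon_id[i])
        lines <- c(lines, paste("chr1", "sim", "exon",
                                tt$start[i], tt$end[i], ".",
                                tt$strand[i], ".", eattr, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a probe-level intensity matrix
#'
#' Probe intensities are drawn as \code{baseline * effect *
#' exp(N(0, noiseSd))} (multiplicative log-normal probe noise around an
#' entity mean), reproducible by seed. Entities without probes are
#' simply absent from the matrix.
#'
#' @param probeEntities data.frame with columns \code{probe_id} and
#'   \code{entity_id} assigning each probe to its entity
#' @param nSamples number of samples (columns)
#' @param effects named numeric vector of per-entity fold effects
#'   (default 1 for entities not named)
#' @param baseline entity baseline intensity (linear scale)
#' @param noiseSd standard deviation of the log-normal probe noise
#' @param seed RNG seed
#' @return numeric matrix, probes x samples
#' @export
simulateIntensities <- function(probeEntities, nSamples, effects = NULL,
                                baseline = 100, noiseSd = 0.2, seed = 1L) {
  if (noiseSd < 0)
    stop("noiseSd must be non-negative")
  stopifnot(is.data.frame(probeEntities),
            all(c("probe_id", "entity_id") %in% colnames(probeEntities)))
  set.seed(seed)
  eff <- rep(1, nrow(probeEntities))
  if (!is.null(effects)) {
    k <- match(probeEntities$entity_id, names(effects))
    eff[!is.na(k)] <- effects[k[!is.na(k)]]
  }
  n <- nrow(probeEntities)
  m <- baseline * eff *
    exp(matrix(rnorm(n * nSamples, 0, noiseSd), n, nSamples))
  dimnames(m) <- list(probeEntities$probe_id,
                      sprintf("S%02d", seq_len(nSamples)))
  m
}
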