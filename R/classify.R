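#' Classify probes by the remapping cascade
#'
#' Applies the fixed cascade that turns raw perfect-match hits into one
#' category per probe:
#' \enumerate{
#'   \item spliced protein-coding transcripts -> \code{mRNA};
#'   \item spliced noncoding-biotype transcripts of the annotation ->
#'     \code{ncRNA};
#'   \item an external ncRNA sequence collection (if supplied) ->
#'     \code{ncRNA};
#'   \item pre-mRNA locus sequences, keeping only hits falling wholly
#'     outside the exons of every transcript of the locus ->
#'     \code{intronic_putative_ncRNA} (intron-only probes measure
#'     putative exons of unannotated isoforms);
#'   \item otherwise \code{NA}.
#' }
#' A probe enters stage k+1 only if it had zero qualifying hits at all
#' earlier stages, so known RNAs always take precedence over intronic
#' placement. All hit identifiers at the deciding stage are recorded;
#' exon ids are recorded only for mRNA hits contained in a single exon
#' (junction-spanning hits contribute the \code{junction} flag instead,
#' and remain transcript evidence).
#'
#' Flags: \code{gene_unique} (exactly one annotation gene locus),
#' \code{transcript_specific} (exactly one transcript),
#' \code{exon_specific} (exactly one exon and not junction-spanning),
#' \code{junction} (any mRNA hit projects to >1 genomic block),
#' \code{multi_hit} (some target carries the probe more than once;
#' multiple occurrences within one target collapse to a single
#' membership). The display \code{color} follows
#' \code{\link{assignColor}}.
#'
#' @param probes data.frame of probes (\code{\link{readProbes}})
#' @param annot a \linkS4class{GenomeAnnotation}
#' @param genome genome sequences (DNAStringSet, named character, or
#'   FASTA path); the spliced and pre-mRNA target sequences are
#'   extracted from it
#' @param ncrna optional external ncRNA collection (named character,
#'   DNAStringSet or FASTA path)
#' @param searchRevcomp match both orientations (default TRUE)
#' @param intronStage run the pre-mRNA intron stage (default TRUE)
#' @return data.frame, one row per input probe, in input order: columns
#'   probe_id, category (\code{"mRNA"}, \code{"ncRNA"},
#'   \code{"intronic_putative_ncRNA"}, \code{"NA"}), semicolon-joined id
#'   sets genes / transcripts / exons / ncrna_targets, and flags
#'   junction, multi_hit, gene_unique, transcript_specific,
#'   exon_specific, color
#' @export
classifyProbes <- function(probes, annot, genome = NULL, ncrna = NULL,
                           searchRevcomp = TRUE, intronStage = TRUE) {
  stopifnot(is.data.frame(probes), is(annot, "GenomeAnnotation"))
  if (is.null(genome))
    stop("configuration error: genome sequence required",
         if (intronStage) " (spliced and intron stages)" else " (spliced stages)")
  genome <- .asGenome(genome)
  if (!is.null(ncrna)) ncrna <- .asTargets(.asGenome(ncrna))

  lens <- unique(nchar(probes$sequence))
  tx <- annot@transcripts
  res <- .emptyAssignments(probes$probe_id)

  splice <- function(tids) {
    if (length(tids) == 0) return(character(0))
    s <- vapply(tids, function(t) extractTranscriptSequence(annot, genome, t),
                character(1))
    names(s) <- tids
    s
  }

  remaining <- probes
  # stage 1: spliced protein-coding transcripts
  codingT <- tx$transcript_id[tx$biotype == "protein_coding"]
  if (length(codingT) && nrow(remaining)) {
    hits <- mapProbes(remaining,
                      buildIndex(splice(codingT), lens),
                      searchRevcomp, targetKind = "mRNA")
    res <- .applyMrnaStage(res, hits, annot, nchar(probes$sequence))
    remaining <- remaining[!(remaining$probe_id %in% hits$probe_id), ,
                           drop = FALSE]
  }
  # stage 2: annotation noncoding transcripts
  ncT <- tx$transcript_id[tx$biotype != "protein_coding"]
  if (length(ncT) && nrow(remaining)) {
    hits <- mapProbes(remaining, buildIndex(splice(ncT), lens),
                      searchRevcomp, targetKind = "mRNA")
    res <- .applyNcStage(res, hits, annot, external = FALSE)
    remaining <- remaining[!(remaining$probe_id %in% hits$probe_id), ,
                           drop = FALSE]
  }
  # stage 3: external ncRNA collection
  if (!is.null(ncrna) && length(ncrna) && nrow(remaining)) {
    hits <- mapProbes(remaining, buildIndex(ncrna, lens),
                      searchRevcomp, targetKind = "ncRNA_db")
    res <- .applyNcStage(res, hits, annot, external = TRUE)
    remaining <- remaining[!(remaining$probe_id %in% hits$probe_id), ,
                           drop = FALSE]
  }
  # stage 4: pre-mRNA locus sequences, intron-only hits
  if (intronStage && nrow(remaining)) {
    gids <- annot@genes$gene_id
    pre <- vapply(gids, function(g) extractPremrnaSequence(annot, genome, g),
                  character(1))
    names(pre) <- gids
    hits <- mapProbes(remaining, buildIndex(pre, lens),
                      searchRevcomp, targetKind = "pre_mRNA")
    res <- .applyIntronStage(res, hits, annot, nchar(probes$sequence))
  }
  res$color <- assignColor(res)
  res
}

.emptyAssignments <- function(probeIds) {
  data.frame(probe_id = probeIds, category = "NA",
             genes = "", transcripts = "", exons = "", ncrna_targets = "",
             junction = FALSE, multi_hit = FALSE, gene_unique = FALSE,
             transcript_specific = FALSE, exon_specific = FALSE,
             color = "black", stringsAsFactors = FALSE)
}

# flat exon table split by transcript (rank order), for fast projection
.txTables <- function(annot) {
  ex <- annot@exons
  tab <- data.frame(start = GenomicRanges::start(ex), end = end(ex),
                    exon_id = ex$exon_id, rank = ex$rank,
                    strand = as.character(strand(ex)),
                    stringsAsFactors = FALSE)
  tabs <- split(tab, ex$transcript_id)
  lapply(tabs, function(d) d[order(d$rank), , drop = FALSE])
}

# transcript interval -> genomic blocks, plain arithmetic on a .txTables
# entry; returns data.frame(gs, ge, exon_id), one row per block
.blocksLocal <- function(tab, qs, width) {
  w <- tab$end - tab$start + 1L
  cumEnd <- cumsum(w)
  cumStart <- cumEnd - w + 1L
  qe <- qs + width - 1L
  hit <- which(cumEnd >= qs & cumStart <= qe)
  minus <- tab$strand[1] == "-"
  o1 <- pmax(qs, cumStart[hit]) - cumStart[hit] + 1L
  o2 <- pmin(qe, cumEnd[hit]) - cumStart[hit] + 1L
  if (minus) {
    data.frame(gs = tab$end[hit] - o2 + 1L, ge = tab$end[hit] - o1 + 1L,
               exon_id = tab$exon_id[hit], stringsAsFactors = FALSE)
  } else {
    data.frame(gs = tab$start[hit] + o1 - 1L, ge = tab$start[hit] + o2 - 1L,
               exon_id = tab$exon_id[hit], stringsAsFactors = FALSE)
  }
}

.applyMrnaStage <- function(res, hits, annot, probeLens) {
  if (nrow(hits) == 0) return(res)
  txTabs <- .txTables(annot)
  txGene <- annot@transcripts$gene_id
  names(txGene) <- annot@transcripts$transcript_id
  for (pid in unique(hits$probe_id)) {
    h <- hits[hits$probe_id == pid, , drop = FALSE]
    i <- match(pid, res$probe_id)
    L <- probeLens[i]
    tids <- sort(unique(h$target_id))
    gids <- sort(unique(unname(txGene[tids])))
    junction <- FALSE
    exonIds <- character(0)
    for (k in seq_len(nrow(h))) {
      blocks <- .blocksLocal(txTabs[[h$target_id[k]]], h$offset[k], L)
      if (nrow(blocks) > 1L) {
        junction <- TRUE
      } else {
        exonIds <- c(exonIds, blocks$exon_id)
      }
    }
    exonIds <- sort(unique(exonIds))
    res$category[i] <- "mRNA"
    res$genes[i] <- paste(gids, collapse = ";")
    res$transcripts[i] <- paste(tids, collapse = ";")
    res$exons[i] <- paste(exonIds, collapse = ";")
    res$junction[i] <- junction
    res$multi_hit[i] <- anyDuplicated(paste(h$target_id)) > 0
    res$gene_unique[i] <- length(gids) == 1L
    res$transcript_specific[i] <- length(tids) == 1L && length(gids) == 1L
    res$exon_specific[i] <- length(exonIds) == 1L && !junction
  }
  res
}

.applyNcStage <- function(res, hits, annot, external) {
  if (nrow(hits) == 0) return(res)
  txGene <- annot@transcripts$gene_id
  names(txGene) <- annot@transcripts$transcript_id
  for (pid in unique(hits$probe_id)) {
    h <- hits[hits$probe_id == pid, , drop = FALSE]
    i <- match(pid, res$probe_id)
    tids <- sort(unique(h$target_id))
    res$category[i] <- "ncRNA"
    res$ncrna_targets[i] <- paste(tids, collapse = ";")
    res$multi_hit[i] <- anyDuplicated(paste(h$target_id)) > 0
    if (!external) {
      # annotation-derived ncRNA transcripts keep their gene locus link
      gids <- sort(unique(unname(txGene[tids])))
      res$genes[i] <- paste(gids, collapse = ";")
      res$gene_unique[i] <- length(gids) == 1L
    }
  }
  res
}

.applyIntronStage <- function(res, hits, annot, probeLens) {
  if (nrow(hits) == 0) return(res)
  g <- annot@genes
  gStart <- GenomicRanges::start(g); gEnd <- end(g)
  gStrand <- as.character(strand(g))
  names(gStart) <- names(gEnd) <- names(gStrand) <- g$gene_id
  ex <- annot@exons
  exByGene <- split(data.frame(start = GenomicRanges::start(ex),
                               end = end(ex)), ex$gene_id)
  for (pid in unique(hits$probe_id)) {
    h <- hits[hits$probe_id == pid, , drop = FALSE]
    i <- match(pid, res$probe_id)
    L <- probeLens[i]
    intronGenes <- character(0)
    for (k in seq_len(nrow(h))) {
      gid <- h$target_id[k]
      # pre-mRNA sequences are strand-oriented; convert the hit offset
      # back to genomic coordinates
      if (gStrand[gid] == "-") {
        ge <- gEnd[gid] - h$offset[k] + 1L
        gs <- ge - L + 1L
      } else {
        gs <- gStart[gid] + h$offset[k] - 1L
        ge <- gs + L - 1L
      }
      et <- exByGene[[gid]]
      if (!any(et$start <= ge & et$end >= gs))
        intronGenes <- c(intronGenes, gid)
    }
    intronGenes <- sort(unique(intronGenes))
    if (length(intronGenes)) {
      res$category[i] <- "intronic_putative_ncRNA"
      res$genes[i] <- paste(intronGenes, collapse = ";")
    }
  }
  res
}

#' Display color of a probe assignment
#'
#' The four-color ambiguity code used for display: \code{green} = mRNA,
#' single gene locus and single transcript; \code{yellow} = mRNA, single
#' locus but several transcripts; \code{red} = mRNA mapping to more than
#' one gene locus (ambiguous, cross-hybridizing); \code{black} = every
#' non-mRNA category (ncRNA, intron-only, unassigned). This mapping is a
#' documented convention of the package.
#'
#' @param assignments data.frame from \code{\link{classifyProbes}} (only
#'   \code{category}, \code{gene_unique}, \code{transcript_specific} are
#'   used)
#' @return character vector of colors
#' @export
assignColor <- function(assignments) {
  ifelse(assignments$category != "mRNA", "black",
  ifelse(!assignments$gene_unique, "red",
  ifelse(assignments$transcript_specific, "green", "yellow")))
}

#' Probe category partition
#'
#' Counts and percentages of probes mapped to mRNAs, to ncRNAs (pooling
#' annotation ncRNAs, the external collection and intron-only probes,
#' which may measure putative exons of alternative mRNAs) and unassigned
#' (NA).
#'
#' @param assignments data.frame from \code{\link{classifyProbes}}
#' @return data.frame with columns class, n, pct (percent of total,
#'   2 decimals, round half up)
#' @export
partitionCounts <- function(assignments) {
  if (nrow(assignments) == 0)
    stop("no probe assignments supplied")
  n <- nrow(assignments)
  cnt <- c(mRNA = sum(assignments$category == "mRNA"),
           ncRNA = sum(assignments$category %in%
                         c("ncRNA", "intronic_putative_ncRNA")),
           "NA" = sum(assignments$category == "NA"))
  data.frame(class = names(cnt), n = as.integer(cnt),
             pct = .roundHalfUp(100 * as.integer(cnt) / n, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read probe assignments
#'
#' TSV with a '#'-prefixed header, one row per probe, id sets
#' semicolon-joined, sorted by probe id.
#'
#' @param assignments data.frame from \code{\link{classifyProbes}}
#' @param path file path
#' @return \code{writeAssignments}: the path, invisibly;
#'   \code{readAssignments}: the assignments data.frame
#' @export
writeAssignments <- function(assignments, path) {
  a <- assignments[order(assignments$probe_id), , drop = FALSE]
  .writeTsv(a, path)
}

#' @rdname writeAssignments
#' @export
readAssignments <- function(path) {
  df <- .readTsv(path)
  for (col in c("junction", "multi_hit", "gene_unique",
                "transcript_specific", "exon_specific"))
    df[[col]] <- as.logical(df[[col]])
  df
}
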