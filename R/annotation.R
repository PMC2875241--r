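#' GenomeAnnotation: gene locus / transcript / exon hierarchy
#'
#' Container for a fully linked annotation: gene loci (hull of member
#' exons), transcripts with ordered exons, and one exon record per
#' transcript membership. Coordinates are 1-based closed genomic
#' intervals held in \link[GenomicRanges]{GRanges}, the Bioconductor
#' convention; GTF/GFF3 files (also 1-based inclusive) are read without
#' coordinate shifts. Exon \code{rank} is the order within the transcript,
#' rank 1 being the 5'-most exon in transcript orientation (for minus
#' strand genes, rank 1 is the genomically rightmost exon).
#'
#' Biotypes are collapsed to \code{"protein_coding"} versus
#' \code{"noncoding"}; annotation biotypes not recognized as either are
#' mapped to \code{"noncoding"} with a warning.
#'
#' @slot genes GRanges, one range per gene locus (exon hull) with
#'   metadata columns \code{gene_id}, \code{name}, \code{biotype}.
#' @slot transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{biotype}, \code{n_exons}, \code{spliced_length}.
#' @slot exons GRanges, one range per (transcript, exon) membership with
#'   metadata columns \code{exon_id}, \code{transcript_id}, \code{gene_id},
#'   \code{rank}. The same \code{exon_id} may appear under several
#'   transcripts that share the exon.
#'
#' @seealso \code{\link{loadAnnotation}}
#' @export
setClass("GenomeAnnotation",
         representation(genes = "GRanges",
                        transcripts = "data.frame",
                        exons = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msgs <- character(0)
  ex <- object@exons
  tx <- object@transcripts
  if (nrow(tx) == 0 || length(ex) == 0)
    return("annotation must contain at least one transcript with exons")
  byTx <- split(seq_along(ex), ex$transcript_id)
  for (tid in names(byTx)) {
    i <- byTx[[tid]]
    rk <- sort(ex$rank[i])
    if (!identical(rk, seq_along(i)))
      msgs <- c(msgs, sprintf("transcript %s: exon ranks not consecutive 1..n", tid))
    if (length(i) > 1 &&
        !isDisjoint(ranges(ex[i])))
      msgs <- c(msgs, sprintf("transcript %s: overlapping exons", tid))
  }
  # gene span must be the exon hull
  hull <- unlist(range(split(ranges(ex), ex$gene_id)))
  g <- object@genes
  hull <- hull[g$gene_id]
  if (any(start(g) != start(hull)) || any(end(g) != end(hull)))
    msgs <- c(msgs, "gene span differs from member-exon hull")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GenomeAnnotation-class compact summary
#' @param object a GenomeAnnotation
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d gene loci, %d transcripts, %d distinct exons\n",
              nGenes(object), nTranscripts(object), nExons(object)))
  bt <- table(object@genes$biotype)
  cat("  gene biotypes:",
      paste(sprintf("%s=%d", names(bt), as.integer(bt)), collapse = ", "), "\n")
})

#' Accessors for GenomeAnnotation
#'
#' \code{geneLoci} returns the gene-level GRanges (one range per locus,
#' exon hull), \code{transcriptInfo} the transcript table,
#' \code{exonRanges} the per-membership exon GRanges. \code{nGenes},
#' \code{nTranscripts} and \code{nExons} count loci, transcripts and
#' distinct exon ids.
#'
#' @param x a \linkS4class{GenomeAnnotation}
#' @return see description
#' @export
setGeneric("geneLoci", function(x) standardGeneric("geneLoci"))
#' @rdname geneLoci
#' @export
setGeneric("transcriptInfo", function(x) standardGeneric("transcriptInfo"))
#' @rdname geneLoci
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname geneLoci
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname geneLoci
#' @export
setGeneric("nTranscripts", function(x) standardGeneric("nTranscripts"))
#' @rdname geneLoci
#' @export
setGeneric("nExons", function(x) standardGeneric("nExons"))

#' @rdname geneLoci
setMethod("geneLoci", "GenomeAnnotation", function(x) x@genes)
#' @rdname geneLoci
setMethod("transcriptInfo", "GenomeAnnotation", function(x) x@transcripts)
#' @rdname geneLoci
setMethod("exonRanges", "GenomeAnnotation", function(x) x@exons)
#' @rdname geneLoci
setMethod("nGenes", "GenomeAnnotation", function(x) length(x@genes))
#' @rdname geneLoci
setMethod("nTranscripts", "GenomeAnnotation", function(x) nrow(x@transcripts))
#' @rdname geneLoci
setMethod("nExons", "GenomeAnnotation", function(x) length(unique(x@exons$exon_id)))

.knownCoding <- "protein_coding"
.knownNoncoding <- c("noncoding", "lincRNA", "lncRNA", "miRNA", "snoRNA",
                     "snRNA", "rRNA", "tRNA", "misc_RNA", "antisense",
                     "processed_transcript", "pseudogene", "ncRNA")

.normalizeBiotype <- function(bt) {
  bt <- as.character(bt)
  bt[is.na(bt)] <- "missing"
  out <- ifelse(bt %in% .knownCoding, "protein_coding", "noncoding")
  unknown <- setdiff(unique(bt), c(.knownCoding, .knownNoncoding))
  if (length(unknown))
    warning("unknown biotype(s) mapped to 'noncoding': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  out
}

# Assemble a GenomeAnnotation from a flat exon membership table with
# columns chrom, start, end, strand, gene_id, gene_name, transcript_id,
# exon_id, rank, biotype (already normalized).
.makeAnnotation <- function(tab) {
  o <- order(tab$transcript_id, tab$rank)
  tab <- tab[o, , drop = FALSE]
  ex <- GRanges(tab$chrom,
                IRanges(tab$start, tab$end),
                strand = tab$strand,
                exon_id = tab$exon_id,
                transcript_id = tab$transcript_id,
                gene_id = tab$gene_id,
                rank = as.integer(tab$rank))
  width <- tab$end - tab$start + 1L
  spl <- tapply(width, tab$transcript_id, sum)
  nEx <- tapply(tab$exon_id, tab$transcript_id, length)
  txGene <- tapply(tab$gene_id, tab$transcript_id, function(g) g[1])
  txBio <- tapply(tab$biotype, tab$transcript_id, function(b) b[1])
  tids <- sort(unique(tab$transcript_id))
  tx <- data.frame(transcript_id = tids,
                   gene_id = as.character(txGene[tids]),
                   biotype = as.character(txBio[tids]),
                   n_exons = as.integer(nEx[tids]),
                   spliced_length = as.integer(spl[tids]),
                   stringsAsFactors = FALSE)
  gids <- sort(unique(tab$gene_id))
  gChrom <- tapply(tab$chrom, tab$gene_id, function(x) x[1])
  gStrand <- tapply(as.character(tab$strand), tab$gene_id, function(x) x[1])
  gStart <- tapply(tab$start, tab$gene_id, min)
  gEnd <- tapply(tab$end, tab$gene_id, max)
  gName <- tapply(tab$gene_name, tab$gene_id, function(x) x[1])
  # a locus biotype is protein_coding if any member transcript is
  gBio <- tapply(tab$biotype, tab$gene_id,
                 function(b) if (any(b == "protein_coding")) "protein_coding" else "noncoding")
  genes <- GRanges(as.character(gChrom[gids]),
                   IRanges(as.integer(gStart[gids]), as.integer(gEnd[gids])),
                   strand = as.character(gStrand[gids]),
                   gene_id = gids,
                   name = as.character(gName[gids]),
                   biotype = as.character(gBio[gids]))
  names(genes) <- gids
  new("GenomeAnnotation", genes = genes, transcripts = tx, exons = ex)
}

#' Load a GTF/GFF3 annotation
#'
#' Reads exon features (attribute keys \code{gene_id},
#' \code{transcript_id}, \code{exon_number}/\code{rank},
#' \code{gene_biotype}/\code{biotype}) into a fully linked
#' \linkS4class{GenomeAnnotation}. File coordinates are 1-based inclusive
#' and are retained as such (GRanges convention). A \code{transcript}
#' feature without any exon feature is a validation error; biotypes other
#' than \code{protein_coding} and the common noncoding classes raise a
#' warning and are treated as noncoding.
#'
#' @param path GTF or GFF3 file
#' @param format passed to \code{\link[rtracklayer]{import}}; guessed from
#'   the file extension by default
#' @return a \linkS4class{GenomeAnnotation}
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "ProbeRemap")
#' loadAnnotation(gtf)
#' @export
loadAnnotation <- function(path, format = NA) {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  gr <- tryCatch({
    if (is.na(format)) rtracklayer::import(path)
    else rtracklayer::import(path, format = format)
  }, error = function(e) {
    stop("annotation parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0)
    stop("annotation contains no exon features: ", path)
  m <- mcols(ex)
  need <- c("gene_id", "transcript_id")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    stop("exon features lack required attribute(s): ",
         paste(miss, collapse = ", "))
  # transcripts declared but exon-less are invalid
  txFeat <- gr[type %in% c("transcript", "mRNA")]
  if (length(txFeat)) {
    declared <- unique(as.character(txFeat$transcript_id))
    orphan <- setdiff(declared, unique(as.character(m$transcript_id)))
    if (length(orphan))
      stop("transcript(s) with zero exons: ", paste(orphan, collapse = ", "))
  }
  rank <- if ("exon_number" %in% colnames(m)) as.integer(as.character(m$exon_number))
          else if ("rank" %in% colnames(m)) as.integer(as.character(m$rank))
          else NA_integer_
  bt <- if ("gene_biotype" %in% colnames(m)) as.character(m$gene_biotype)
        else if ("biotype" %in% colnames(m)) as.character(m$biotype)
        else if ("transcript_biotype" %in% colnames(m)) as.character(m$transcript_biotype)
        else NA_character_
  eid <- if ("exon_id" %in% colnames(m)) as.character(m$exon_id)
         else sprintf("%s:%d-%d:%s", as.character(seqnames(ex)),
                      start(ex), end(ex), as.character(strand(ex)))
  gname <- if ("gene_name" %in% colnames(m)) as.character(m$gene_name)
           else as.character(m$gene_id)
  tab <- data.frame(chrom = as.character(seqnames(ex)),
                    start = start(ex), end = end(ex),
                    strand = as.character(strand(ex)),
                    gene_id = as.character(m$gene_id),
                    gene_name = gname,
                    transcript_id = as.character(m$transcript_id),
                    exon_id = eid,
                    rank = rank,
                    biotype = .normalizeBiotype(bt),
                    stringsAsFactors = FALSE)
  if (anyNA(tab$rank)) {
    # derive rank from genomic order, 5'-most first in transcript orientation
    tab <- do.call(rbind, lapply(split(tab, tab$transcript_id), function(d) {
      o <- order(d$start)
      if (d$strand[1] == "-") o <- rev(o)
      d <- d[o, , drop = FALSE]
      d$rank <- seq_len(nrow(d))
      d
    }))
  }
  .makeAnnotation(tab)
}

.asGenome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- readDNAStringSet(genome)
  if (is.character(genome))
    genome <- DNAStringSet(toupper(genome))
  if (!is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet, a named character vector, or a FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

.transcriptExons <- function(annot, transcriptId) {
  ex <- annot@exons[annot@exons$transcript_id == transcriptId]
  if (length(ex) == 0)
    stop("unknown transcript: ", transcriptId)
  ex[order(ex$rank)]
}

.checkBounds <- function(gr, genome) {
  chrs <- as.character(seqnames(gr))
  bad <- !(chrs %in% names(genome))
  if (any(bad))
    stop("coordinate error: chromosome(s) absent from genome: ",
         paste(unique(chrs[bad]), collapse = ", "))
  lens <- width(genome)[match(chrs, names(genome))]
  if (any(start(gr) < 1L) || any(end(gr) > lens))
    stop("coordinate error: exon interval beyond chromosome bounds")
}

#' Extract the spliced (mature) sequence of a transcript
#'
#' Exon subsequences are concatenated in rank order; for minus-strand
#' transcripts the concatenation is reverse-complemented as a whole.
#' The result is uppercase.
#'
#' @param annot a \linkS4class{GenomeAnnotation}
#' @param genome DNAStringSet, named character vector, or FASTA path
#' @param transcriptId transcript identifier
#' @return a character string of length \code{spliced_length}
#' @export
extractTranscriptSequence <- function(annot, genome, transcriptId) {
  genome <- .asGenome(genome)
  ex <- .transcriptExons(annot, transcriptId)
  .checkBounds(ex, genome)
  exg <- ex[order(start(ex))]         # genomic order
  chr <- genome[[as.character(seqnames(exg))[1]]]
  parts <- lapply(seq_along(exg),
                  function(i) subseq(chr, start(exg)[i], end(exg)[i]))
  seqcat <- do.call(Biostrings::xscat, parts)
  if (as.character(strand(exg))[1] == "-")
    seqcat <- reverseComplement(seqcat)
  toupper(as.character(seqcat))
}

#' Extract the pre-mRNA (locus) sequence of a gene
#'
#' The contiguous genomic sequence of the locus span (exon hull, introns
#' included), reverse-complemented for minus-strand genes so that the
#' returned string reads 5' to 3' in transcript orientation.
#'
#' @inheritParams extractTranscriptSequence
#' @param geneId gene identifier
#' @return a character string covering the locus span
#' @export
extractPremrnaSequence <- function(annot, genome, geneId) {
  genome <- .asGenome(genome)
  g <- annot@genes[annot@genes$gene_id == geneId]
  if (length(g) == 0)
    stop("unknown gene: ", geneId)
  .checkBounds(g, genome)
  chr <- genome[[as.character(seqnames(g))]]
  s <- subseq(chr, start(g), end(g))
  if (as.character(strand(g)) == "-")
    s <- reverseComplement(s)
  toupper(as.character(s))
}

#' Project a transcript interval onto the genome
#'
#' Maps a 1-based interval on the spliced transcript to one or more
#' genomic blocks. The result has more than one block exactly when the
#' interval crosses an exon-exon junction; block widths always sum to
#' \code{width}. Blocks are returned in genomic order.
#'
#' @param annot a \linkS4class{GenomeAnnotation}
#' @param transcriptId transcript identifier
#' @param start 1-based start position on the spliced transcript
#' @param width interval width in nt
#' @return a GRanges of genomic blocks
#' @export
projectToGenome <- function(annot, transcriptId, start, width) {
  ex <- .transcriptExons(annot, transcriptId)
  w <- GenomicRanges::width(ex)
  total <- sum(w)
  if (start < 1L || width < 1L || start + width - 1L > total)
    stop("coordinate error: interval [", start, ", ", start + width - 1L,
         "] outside spliced transcript of length ", total)
  qs <- start; qe <- start + width - 1L
  cumEnd <- cumsum(w)
  cumStart <- cumEnd - w + 1L
  hit <- which(cumEnd >= qs & cumStart <= qe)
  minus <- as.character(strand(ex))[1] == "-"
  blocks <- lapply(hit, function(i) {
    o1 <- max(qs, cumStart[i]) - cumStart[i] + 1L   # offsets within exon,
    o2 <- min(qe, cumEnd[i]) - cumStart[i] + 1L     # transcript orientation
    if (minus) {
      IRanges(end(ex)[i] - o2 + 1L, end(ex)[i] - o1 + 1L)
    } else {
      IRanges(GenomicRanges::start(ex)[i] + o1 - 1L,
              GenomicRanges::start(ex)[i] + o2 - 1L)
    }
  })
  ir <- do.call(c, blocks)
  gr <- GRanges(as.character(seqnames(ex))[1], ir,
                strand = as.character(strand(ex))[1])
  sort(gr, ignore.strand = TRUE)
}

#' Map genomic positions to transcript coordinates
#'
#' Inverse of \code{\link{projectToGenome}} at single-base resolution:
#' for each genomic position, the 1-based coordinate on the spliced
#' transcript, or \code{NA} for positions outside the transcript's exons.
#'
#' @inheritParams projectToGenome
#' @param pos vector of genomic positions (same chromosome as the transcript)
#' @return integer vector of transcript coordinates
#' @export
genomeToTranscript <- function(annot, transcriptId, pos) {
  ex <- .transcriptExons(annot, transcriptId)
  w <- GenomicRanges::width(ex)
  cumStart <- cumsum(w) - w + 1L
  minus <- as.character(strand(ex))[1] == "-"
  vapply(pos, function(p) {
    i <- which(GenomicRanges::start(ex) <= p & end(ex) >= p)
    if (length(i) == 0) return(NA_integer_)
    i <- i[1]
    o <- if (minus) end(ex)[i] - p + 1L else p - GenomicRanges::start(ex)[i] + 1L
    as.integer(cumStart[i] + o - 1L)
  }, integer(1))
}

#' Intron intervals of a gene locus
#'
#' The locus span minus the union of all member-transcript exons.
#'
#' @inheritParams extractPremrnaSequence
#' @return a GRanges of intronic intervals (possibly empty)
#' @export
intronRanges <- function(annot, geneId) {
  g <- annot@genes[annot@genes$gene_id == geneId]
  if (length(g) == 0)
    stop("unknown gene: ", geneId)
  ex <- annot@exons[annot@exons$gene_id == geneId]
  GenomicRanges::setdiff(g, reduce(ex, ignore.strand = TRUE),
                         ignore.strand = TRUE)
}
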