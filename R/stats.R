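#' Mapping coverage of annotation entities
#'
#' Coverage is the proportion of annotation entities (gene loci or
#' transcripts) hit by the probes of an array. "All mapped" counts
#' entities hit by at least one probe regardless of ambiguity; "unique
#' mapped" counts entities targeted by at least one probe that maps to
#' no other entity at that level (with \code{strict = TRUE}, entities
#' all of whose probes are unambiguous). Entity hits are taken from the
#' spliced-transcript stages of the cascade (protein-coding and
#' annotation noncoding); intron-only probes do not mark their locus as
#' covered, since they are classified as putative ncRNAs rather than as
#' gene hits.
#'
#' @param assignments data.frame from \code{\link{classifyProbes}}
#' @param annot the \linkS4class{GenomeAnnotation} supplying total entity
#'   counts
#' @param level \code{"transcript"} or \code{"gene"}
#' @param array array label for the output row
#' @param strict require all probes of an entity to be unambiguous
#' @return one-row data.frame: array, level, n_unique_mapped,
#'   pct_unique_mapped, n_all_mapped, pct_all_mapped, n_total_entities
#'   (percentages of the total, 2 decimals, round half up)
#' @export
coverageStats <- function(assignments, annot,
                          level = c("transcript", "gene"),
                          array = "array", strict = FALSE) {
  level <- match.arg(level)
  if (nGenes(annot) == 0)
    stop("empty annotation")
  hitSets <- .entityHitSets(assignments, annot, level)
  nTotal <- if (level == "gene") nGenes(annot) else nTranscripts(annot)
  allMapped <- unique(unlist(hitSets))
  singles <- hitSets[lengths(hitSets) == 1L]
  uniqueByOne <- unique(unlist(singles))
  if (strict) {
    multiHit <- unique(unlist(hitSets[lengths(hitSets) > 1L]))
    uniqueMapped <- setdiff(uniqueByOne, multiHit)
  } else {
    uniqueMapped <- uniqueByOne
  }
  coverageFromCounts(array, level, length(uniqueMapped),
                     length(allMapped), nTotal)
}

#' @describeIn coverageStats build a coverage row directly from counts
#'   (e.g. to recompute the percentages of a published coverage table)
#' @param nUnique,nAll,nTotal entity counts
#' @export
coverageFromCounts <- function(array, level, nUnique, nAll, nTotal) {
  if (!(nUnique <= nAll && nAll <= nTotal))
    stop("invalid counts: need n_unique <= n_all <= n_total")
  data.frame(array = array, level = level,
             n_unique_mapped = as.integer(nUnique),
             pct_unique_mapped = .roundHalfUp(100 * nUnique / nTotal, 2),
             n_all_mapped = as.integer(nAll),
             pct_all_mapped = .roundHalfUp(100 * nAll / nTotal, 2),
             n_total_entities = as.integer(nTotal),
             stringsAsFactors = FALSE)
}

# per-probe entity hit sets at the requested level, from the spliced
# stages (mRNA + annotation ncRNA)
.entityHitSets <- function(assignments, annot, level) {
  a <- assignments
  if (level == "gene") {
    k <- a$category %in% c("mRNA", "ncRNA") & nzchar(a$genes)
    sets <- lapply(a$genes[k], .splitIds)
  } else {
    txIds <- annot@transcripts$transcript_id
    k <- a$category %in% c("mRNA", "ncRNA")
    sets <- lapply(which(k), function(i) {
      if (a$category[i] == "mRNA") .splitIds(a$transcripts[i])
      else intersect(.splitIds(a$ncrna_targets[i]), txIds)
    })
    sets <- sets[lengths(sets) > 0]
  }
  names(sets) <- NULL
  sets
}

#' Mapping efficiency of an array's probes
#'
#' Efficiency is the proportion of an array's probes that map to at
#' least one annotation entity at the requested level; mapped probes are
#' split into those hitting exactly one entity versus more than one
#' (ambiguous).
#'
#' @inheritParams coverageStats
#' @param nProbesTotal total distinct probes of the array
#' @return one-row data.frame: array, level, n_probes_one,
#'   n_probes_multi, pct_one, pct_multi (percent of mapped probes),
#'   n_probes_mapped, n_probes_total, efficiency_pct (percent of total)
#' @export
efficiencyStats <- function(assignments, annot, nProbesTotal,
                            level = c("transcript", "gene"),
                            array = "array") {
  level <- match.arg(level)
  hitSets <- .entityHitSets(assignments, annot, level)
  nOne <- sum(lengths(hitSets) == 1L)
  nMulti <- sum(lengths(hitSets) > 1L)
  if (nProbesTotal < nOne + nMulti)
    stop("validation error: total probes (", nProbesTotal,
         ") smaller than mapped probes (", nOne + nMulti, ")")
  efficiencyFromCounts(array, level, nOne, nMulti, nProbesTotal)
}

#' @describeIn efficiencyStats build an efficiency row directly from
#'   counts (e.g. to recompute the percentages of a published efficiency
#'   table)
#' @param nOne,nMulti counts of probes mapping to exactly one / more than
#'   one entity
#' @export
efficiencyFromCounts <- function(array, level, nOne, nMulti, nProbesTotal) {
  nMapped <- nOne + nMulti
  if (nProbesTotal < nMapped)
    stop("validation error: total probes smaller than mapped probes")
  pctOne <- if (nMapped > 0) .roundHalfUp(100 * nOne / nMapped, 2) else 0
  pctMulti <- if (nMapped > 0) .roundHalfUp(100 * nMulti / nMapped, 2) else 0
  data.frame(array = array, level = level,
             n_probes_one = as.integer(nOne),
             pct_one = pctOne,
             n_probes_multi = as.integer(nMulti),
             pct_multi = pctMulti,
             n_probes_mapped = as.integer(nMapped),
             n_probes_total = as.integer(nProbesTotal),
             efficiency_pct = .roundHalfUp(100 * nMapped / nProbesTotal, 2),
             stringsAsFactors = FALSE)
}

#' GC content of probe sequences
#'
#' Percent G+C over sequence length; ambiguous bases count toward the
#' length only. Two decimals, round half up.
#'
#' @param sequence character vector of nucleotide sequences
#' @return numeric vector of percentages
#' @examples
#' gcContent(c("AAAA", "GCGC"))  # 0, 100
#' @export
gcContent <- function(sequence) {
  if (any(!nzchar(sequence)) || any(is.na(sequence)))
    stop("empty probe sequence")
  gc <- nchar(gsub("[^GCgc]", "", sequence))
  .roundHalfUp(100 * gc / nchar(sequence), 2)
}

#' Write a statistics table as TSV
#' @param stats a data.frame of coverage/efficiency/partition rows
#' @param path output file
#' @return the path, invisibly
#' @export
writeStats <- function(stats, path) .writeTsv(stats, path)
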