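#' Build remapped probe-set definitions
#'
#' Groups probes into redefined summarization units at one of four
#' levels, using only unambiguous evidence:
#' \itemize{
#'   \item \code{gene}: mRNA probes mapping to exactly one gene locus
#'     (gene-unique);
#'   \item \code{transcript}: for each transcript, the gene-unique mRNA
#'     probes hitting it (a probe legitimately appears in several
#'     transcript sets of its unique gene);
#'   \item \code{exon}: gene-unique, non-junction mRNA probes with a
#'     recorded exon hit;
#'   \item \code{ncRNA}: probes of category ncRNA (external collection or
#'     annotation noncoding transcripts, keyed by ncRNA target id) plus
#'     intron-only probes (keyed by their gene locus, the putative ncRNA
#'     host).
#' }
#' Multi-locus (ambiguous) probes are excluded from the gene, transcript
#' and exon levels.
#'
#' @param assignments data.frame from \code{\link{classifyProbes}}
#' @param level one of \code{"gene"}, \code{"transcript"}, \code{"exon"},
#'   \code{"ncRNA"}
#' @param minProbes minimum qualifying probes for a set to be emitted
#'   (default 1)
#' @return data.frame with columns entity_id, level, n_probes and a list
#'   column probe_ids (sorted, duplicate-free), sorted by entity_id
#' @export
buildSets <- function(assignments, level = c("gene", "transcript",
                                             "exon", "ncRNA"),
                      minProbes = 1L) {
  level <- match.arg(level)
  a <- assignments
  pairs <- switch(level,
    gene = {
      k <- a$category == "mRNA" & a$gene_unique
      data.frame(entity = a$genes[k], probe = a$probe_id[k])
    },
    transcript = {
      k <- which(a$category == "mRNA" & a$gene_unique)
      do.call(rbind, lapply(k, function(i)
        data.frame(entity = .splitIds(a$transcripts[i]),
                   probe = a$probe_id[i])))
    },
    exon = {
      k <- which(a$category == "mRNA" & a$gene_unique & !a$junction &
                   nzchar(a$exons))
      do.call(rbind, lapply(k, function(i)
        data.frame(entity = .splitIds(a$exons[i]), probe = a$probe_id[i])))
    },
    ncRNA = {
      k1 <- which(a$category == "ncRNA")
      k2 <- which(a$category == "intronic_putative_ncRNA")
      rbind(
        do.call(rbind, lapply(k1, function(i)
          data.frame(entity = .splitIds(a$ncrna_targets[i]),
                     probe = a$probe_id[i]))),
        do.call(rbind, lapply(k2, function(i)
          data.frame(entity = .splitIds(a$genes[i]),
                     probe = a$probe_id[i]))))
    })
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(entity_id = character(0), level = character(0),
                      n_probes = integer(0),
                      probe_ids = I(list()), stringsAsFactors = FALSE))
  }
  byEnt <- split(pairs$probe, pairs$entity)
  byEnt <- lapply(byEnt, function(p) sort(unique(p)))
  byEnt <- byEnt[vapply(byEnt, length, integer(1)) >= minProbes]
  ids <- sort(names(byEnt))
  if (length(ids) == 0) {
    return(data.frame(entity_id = character(0), level = character(0),
                      n_probes = integer(0),
                      probe_ids = I(list()), stringsAsFactors = FALSE))
  }
  data.frame(entity_id = ids, level = level,
             n_probes = vapply(byEnt[ids], length, integer(1)),
             probe_ids = I(unname(byEnt[ids])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the remapping download files
#'
#' Emits the flat text analogues of the remapped chip-definition
#' downloads into \code{outDir}:
#' \itemize{
#'   \item \code{probes2genes.txt}: gene-unique mRNA probes -> gene;
#'   \item \code{probes2transcripts.txt}: the same probes, one row per
#'     transcript of their unique gene that they hit;
#'   \item \code{probesets2genes.txt}: vendor probeset -> gene when all
#'     of its gene-unique member probes agree on one gene (unanimity;
#'     probesets whose probes disagree are dropped and logged);
#'   \item \code{ambigprobes2genes.txt}: multi-locus mRNA probes with all
#'     hit loci listed;
#'   \item \code{sets_<level>.txt} for each of the four levels: flat
#'     set-definition files (entity_id, n_probes, comma-joined probe
#'     ids), the documented text stand-in for a binary chip-definition
#'     format.
#' }
#' All files are TSV with a '#'-prefixed header and deterministic
#' (sorted) row order, so re-running produces byte-identical output.
#'
#' @param assignments data.frame from \code{\link{classifyProbes}}
#' @param probes probe table (\code{\link{readProbes}}), used for vendor
#'   probeset membership
#' @param outDir output directory (created if absent)
#' @param minProbes passed to \code{\link{buildSets}}
#' @return named character vector of written file paths (the manifest)
#' @export
writeMappingFiles <- function(assignments, probes, outDir, minProbes = 1L) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  a <- assignments
  manifest <- character(0)

  uniq <- a[a$category == "mRNA" & a$gene_unique, , drop = FALSE]
  uniq <- uniq[order(uniq$probe_id), , drop = FALSE]
  p2g <- data.frame(probe_id = uniq$probe_id, gene_id = uniq$genes)
  manifest["probes2genes"] <-
    .writeTsv(p2g, file.path(outDir, "probes2genes.txt"))

  p2t <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(i)
    data.frame(probe_id = uniq$probe_id[i],
               transcript_id = .splitIds(uniq$transcripts[i]))))
  if (is.null(p2t))
    p2t <- data.frame(probe_id = character(0), transcript_id = character(0))
  p2t <- p2t[order(p2t$probe_id, p2t$transcript_id), , drop = FALSE]
  manifest["probes2transcripts"] <-
    .writeTsv(p2t, file.path(outDir, "probes2transcripts.txt"))

  ambig <- a[a$category == "mRNA" & !a$gene_unique, , drop = FALSE]
  ambig <- ambig[order(ambig$probe_id), , drop = FALSE]
  ag <- data.frame(probe_id = ambig$probe_id, gene_ids = ambig$genes)
  manifest["ambigprobes2genes"] <-
    .writeTsv(ag, file.path(outDir, "ambigprobes2genes.txt"))

  # vendor probeset -> gene by unanimity of its gene-unique members
  ps <- probes$probeset_id
  names(ps) <- probes$probe_id
  memb <- split(uniq$genes, unname(ps[uniq$probe_id]))
  memb <- memb[nzchar(names(memb))]
  gene <- vapply(memb, function(g) {
    u <- unique(g)
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  dropped <- names(gene)[is.na(gene)]
  if (length(dropped))
    message("probesets2genes: dropped ", length(dropped),
            " probeset(s) with discordant gene assignment: ",
            paste(dropped, collapse = ", "))
  keep <- !is.na(gene)
  ps2g <- data.frame(probeset_id = names(gene)[keep],
                     gene_id = unname(gene[keep]))
  ps2g <- ps2g[order(ps2g$probeset_id), , drop = FALSE]
  manifest["probesets2genes"] <-
    .writeTsv(ps2g, file.path(outDir, "probesets2genes.txt"))

  for (lvl in c("gene", "transcript", "exon", "ncRNA")) {
    s <- buildSets(a, lvl, minProbes)
    flat <- data.frame(entity_id = s$entity_id, n_probes = s$n_probes,
                       probe_ids = vapply(s$probe_ids, paste,
                                          character(1), collapse = ","))
    manifest[paste0("sets_", lvl)] <-
      .writeTsv(flat, file.path(outDir, paste0("sets_", lvl, ".txt")))
  }
  manifest
}

#' Read a flat set-definition file
#'
#' @param path a \code{sets_<level>.txt} file written by
#'   \code{\link{writeMappingFiles}}
#' @param level level label to record
#' @return data.frame as returned by \code{\link{buildSets}}
#' @export
readSets <- function(path, level = NA_character_) {
  df <- .readTsv(path)
  data.frame(entity_id = df$entity_id, level = level,
             n_probes = as.integer(df$n_probes),
             probe_ids = I(strsplit(df$probe_ids, ",", fixed = TRUE)),
             stringsAsFactors = FALSE)
}
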