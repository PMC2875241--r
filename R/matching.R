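#' ExactMatchIndex: hashed k-mer index for full-length perfect matching
#'
#' Replaces heuristic alignment for the perfect-match-only setting: for
#' every requested probe length L, all L-mers of all target sequences are
#' hashed with their (target, offset) occurrence lists, so a probe lookup
#' is a single hash access. K-mers containing any non-ACGT letter are not
#' indexed (probes containing N can never match).
#'
#' @slot tables list keyed by probe length (as character); each element is
#'   a list with \code{env} (k-mer -> occurrence row indices) and
#'   \code{occ} (data.frame of target_id, offset)
#' @slot lengths integer vector of indexed probe lengths
#' @slot targetNames character vector of target identifiers
#' @seealso \code{\link{buildIndex}}, \code{\link{mapProbes}}
#' @export
setClass("ExactMatchIndex",
         representation(tables = "list",
                        lengths = "integer",
                        targetNames = "character"))

#' @describeIn ExactMatchIndex-class compact summary
#' @param object an ExactMatchIndex
#' @export
setMethod("show", "ExactMatchIndex", function(object) {
  cat(sprintf("ExactMatchIndex: %d target(s), probe length(s) %s\n",
              length(object@targetNames),
              paste(object@lengths, collapse = ", ")))
  for (L in object@lengths) {
    t <- object@tables[[as.character(L)]]
    cat(sprintf("  L=%d: %d positions, %d distinct k-mers\n",
                L, nrow(t$occ), length(t$env)))
  }
})

.asTargets <- function(targets) {
  if (is(targets, "DNAStringSet"))
    targets <- as.character(targets)
  if (length(targets) == 0)
    stop("configuration error: empty target set")
  if (!is.character(targets) || is.null(names(targets)) ||
      any(!nzchar(names(targets))))
    stop("targets must be a named character vector or DNAStringSet")
  toupper(targets)
}

#' Build an exact-match index over target sequences
#'
#' @param targets named character vector or DNAStringSet (id -> sequence)
#' @param probeLengths integer vector of probe lengths to index
#' @return an \linkS4class{ExactMatchIndex}
#' @examples
#' idx <- buildIndex(c(t1 = "ACGTACGT"), 4)
#' mapProbes(data.frame(probe_id = "p1", sequence = "ACGT"), idx)
#' @export
buildIndex <- function(targets, probeLengths) {
  targets <- .asTargets(targets)
  if (length(targets) == 0)
    stop("configuration error: empty target set")
  probeLengths <- sort(unique(as.integer(probeLengths)))
  if (any(probeLengths < 1))
    stop("configuration error: probe lengths must be positive")
  tables <- list()
  for (L in probeLengths) {
    tid <- character(0); off <- integer(0); kmer <- character(0)
    for (nm in names(targets)) {
      s <- targets[[nm]]
      n <- nchar(s)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      km <- substring(s, starts, starts + L - 1L)
      keep <- !grepl("[^ACGT]", km)
      tid <- c(tid, rep(nm, sum(keep)))
      off <- c(off, starts[keep])
      kmer <- c(kmer, km[keep])
    }
    occ <- data.frame(target_id = tid, offset = off, stringsAsFactors = FALSE)
    env <- list2env(split(seq_len(nrow(occ)), kmer), hash = TRUE)
    tables[[as.character(L)]] <- list(env = env, occ = occ)
  }
  new("ExactMatchIndex", tables = tables, lengths = probeLengths,
      targetNames = names(targets))
}

.lookup <- function(table, key) {
  rows <- get0(key, envir = table$env, inherits = FALSE)
  if (is.null(rows)) return(NULL)
  table$occ[rows, , drop = FALSE]
}

#' Map probes by full-length exact matching
#'
#' Returns all and only full-length zero-mismatch occurrences of each
#' probe in the indexed targets. With \code{searchRevcomp} (the default)
#' occurrences of the probe's reverse complement are additionally
#' returned, flagged \code{orientation = "revcomp"}; vendor probe files
#' differ in strand convention, so searching both is lossless. Probes
#' containing N never match. Output is deterministically sorted by
#' probe id, target id, offset and orientation; offsets are 1-based.
#'
#' @param probes data.frame with columns \code{probe_id} and
#'   \code{sequence} (see \code{\link{readProbes}})
#' @param index an \linkS4class{ExactMatchIndex} built for every probe
#'   length present
#' @param searchRevcomp also search the reverse complement
#' @param targetKind label stored in the \code{target_kind} column
#'   (\code{"mRNA"}, \code{"ncRNA_db"} or \code{"pre_mRNA"})
#' @return data.frame of hits: probe_id, target_id, target_kind, offset,
#'   orientation
#' @export
mapProbes <- function(probes, index, searchRevcomp = TRUE,
                      targetKind = NA_character_) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "sequence") %in% colnames(probes)))
  seqs <- toupper(probes$sequence)
  lens <- nchar(seqs)
  missing <- setdiff(unique(lens), index@lengths)
  if (length(missing))
    stop("configuration error: probe length(s) not indexed: ",
         paste(missing, collapse = ", "))
  clean <- !grepl("[^ACGT]", seqs)
  rcseqs <- rep(NA_character_, length(seqs))
  if (searchRevcomp && any(clean))
    rcseqs[clean] <- .revComp(seqs[clean])
  out <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    if (!clean[i]) next
    tab <- index@tables[[as.character(lens[i])]]
    hits <- .lookup(tab, seqs[i])
    if (!is.null(hits) && nrow(hits))
      hits$orientation <- "forward"
    rc <- NULL
    if (searchRevcomp) {
      rc <- .lookup(tab, rcseqs[i])
      if (!is.null(rc) && nrow(rc))
        rc$orientation <- "revcomp"
    }
    h <- rbind(hits, rc)
    if (!is.null(h) && nrow(h)) {
      h$probe_id <- probes$probe_id[i]
      out[[i]] <- h
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(probe_id = character(0), target_id = character(0),
                      target_kind = character(0), offset = integer(0),
                      orientation = character(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, out)
  h$target_kind <- targetKind
  h <- h[, c("probe_id", "target_id", "target_kind", "offset", "orientation")]
  h <- h[order(h$probe_id, h$target_id, h$offset, h$orientation), ,
         drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Read a probe table
#'
#' Tab-separated columns \code{probe_id}, \code{probeset_id},
#' \code{sequence} and optionally \code{array}; a header line is
#' auto-detected (a first line whose third field is not a plain ACGTN
#' string is treated as a header).
#'
#' @param path TSV file
#' @return data.frame with columns probe_id, probeset_id, sequence, array
#' @export
readProbes <- function(path) {
  if (!file.exists(path))
    stop("probe file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  hasHeader <- length(first) >= 3 && grepl("[^ACGTNacgtn]", first[3])
  df <- read.delim(path, header = hasHeader, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  if (ncol(df) < 3)
    stop("probe file must have at least 3 columns (probe_id, probeset_id, sequence)")
  df <- df[, 1:min(4, ncol(df)), drop = FALSE]
  colnames(df)[1:3] <- c("probe_id", "probeset_id", "sequence")
  if (ncol(df) == 3) df$array <- character(nrow(df))
  else colnames(df)[4] <- "array"
  df$sequence <- toupper(df$sequence)
  bad <- !nzchar(df$sequence) | grepl("[^ACGTN]", df$sequence)
  if (any(bad))
    stop("invalid probe sequence(s) for: ",
         paste(utils::head(df$probe_id[bad], 5), collapse = ", "))
  df
}

#' Write probe hits as TSV
#' @param hits data.frame from \code{\link{mapProbes}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeHits <- function(hits, path) .writeTsv(hits, path)
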