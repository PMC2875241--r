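#' Read a probe-level intensity matrix
#'
#' TSV of linear-scale intensities, probes in rows, samples in columns,
#' header row of sample ids, first column probe ids.
#'
#' @param path TSV file
#' @return numeric matrix with probe row names and sample column names
#' @export
readIntensityMatrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  mode(m) <- "numeric"
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe ids in intensity matrix")
  if (any(m < 0, na.rm = TRUE))
    stop("negative intensities in matrix")
  m
}

#' Summarize probe intensities to entity-level signals
#'
#' For each probe set, the entity signal per sample is the log2 of the
#' arithmetic mean of the member-probe intensities on the linear scale
#' (the global-signal definition; \code{scale = "log2"} gives the common
#' alternative, the mean of per-probe log2 values). Means are clipped at
#' \code{floor} (default 1.0) before the log so that all-zero probe
#' vectors yield a finite signal; clipping is logged. Probes referenced
#' by a set but absent from the matrix are dropped with a warning, and
#' entities with no present probes are omitted.
#'
#' @param mat intensity matrix (probes x samples, linear scale)
#' @param sets probe-set definitions from \code{\link{buildSets}}
#' @param scale \code{"linear"} (mean then log2) or \code{"log2"} (mean
#'   of log2)
#' @param floor lower clip applied before taking log2
#' @return matrix of signals, entities x samples
#' @examples
#' m <- matrix(c(4, 4, 4), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
#' s <- data.frame(entity_id = "g1", level = "gene", n_probes = 3,
#'                 probe_ids = I(list(paste0("p", 1:3))))
#' summarizeSets(m, s)  # log2(4) = 2
#' @export
summarizeSets <- function(mat, sets, scale = c("linear", "log2"),
                          floor = 1.0) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(mat))
  rows <- list()
  clipped <- 0L
  for (i in seq_len(nrow(sets))) {
    pids <- sets$probe_ids[[i]]
    present <- intersect(pids, rownames(mat))
    if (length(present) < length(pids))
      warning("entity ", sets$entity_id[i], ": ",
              length(pids) - length(present),
              " probe(s) absent from the intensity matrix", call. = FALSE)
    if (length(present) == 0) next
    sub <- mat[present, , drop = FALSE]
    if (scale == "linear") {
      m <- colMeans(sub)
      clipped <- clipped + sum(m < floor)
      sig <- log2(pmax(m, floor))
    } else {
      sig <- colMeans(log2(pmax(sub, floor)))
      clipped <- clipped + sum(sub < floor)
    }
    rows[[sets$entity_id[i]]] <- sig
  }
  if (clipped > 0)
    message("summarizeSets: ", clipped, " value(s) clipped at floor ", floor)
  if (length(rows) == 0)
    return(matrix(numeric(0), 0, ncol(mat),
                  dimnames = list(NULL, colnames(mat))))
  do.call(rbind, rows)
}

#' Per-probe expression profile
#'
#' Raw probe-level rows in a requested sample order (the per-probe
#' expression view as a table).
#'
#' @param mat intensity matrix
#' @param probeIds probes to extract
#' @param sampleOrder column order (default: as in the matrix)
#' @return numeric matrix, probes x samples
#' @export
probeProfile <- function(mat, probeIds, sampleOrder = colnames(mat)) {
  unknown <- setdiff(probeIds, rownames(mat))
  if (length(unknown))
    stop("unknown probe id(s): ", paste(unknown, collapse = ", "))
  unknownS <- setdiff(sampleOrder, colnames(mat))
  if (length(unknownS))
    stop("unknown sample id(s): ", paste(unknownS, collapse = ", "))
  mat[probeIds, sampleOrder, drop = FALSE]
}
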