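# Per-column conservation profiling and consensus-signature derivation.

#' Per-column conservation profile of an alignment
#'
#' For each alignment column: the modal residue among occupied rows (ties
#' broken alphabetically), the identity fraction (modal count / occupied
#' rows) and the occupancy fraction (occupied rows / rows).
#'
#' @param alignment gapped `AAStringSet`.
#' @return data.frame with columns `column`, `modal`, `identity`,
#'   `occupancy`.
#' @export
conservationProfile <- function(alignment) {
  m <- do.call(rbind, strsplit(as.character(alignment), ""))
  L <- ncol(m)
  rows <- nrow(m)
  out <- data.frame(column = seq_len(L), modal = NA_character_,
                    identity = NA_real_, occupancy = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    col <- m[, j]
    occ <- col[col != "-"]
    out$occupancy[j] <- length(occ) / rows
    if (length(occ) == 0L) { out$identity[j] <- 0; next }
    tab <- sort(table(occ), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    out$modal[j] <- sort(top)[1]
    out$identity[j] <- max(tab) / length(occ)
  }
  out
}

#' Derive a consensus signature with spacer notation
#'
#' Columns whose identity fraction reaches `invariantThreshold` (and whose
#' occupancy reaches `minOccupancy`) emit their modal residue as an anchor;
#' maximal runs of non-conserved columns emit a bounded spacer `Xn` whose
#' bounds are the minimum and maximum number of residues (per row, gaps
#' collapsed) spanning the run — mixed 7- and 8-residue spacers therefore
#' render as `X7-8`. Leading and trailing spacer runs are trimmed so the
#' result is itself a valid spacing-grammar expression.
#'
#' @param alignment gapped `AAStringSet`.
#' @param invariantThreshold identity fraction a column must reach to count
#'   as invariant (default 1.0 = strict invariance among occupied rows).
#' @param minOccupancy occupancy floor for anchor columns (default 0.9).
#' @param region optional `c(start, end)` column window (1-based inclusive).
#' @return the signature as a pattern expression string (parseable by
#'   [parsePattern()]), or `""` when no column is conserved.
#' @export
consensusSignature <- function(alignment, invariantThreshold = 1.0,
                               minOccupancy = 0.9, region = NULL) {
  m <- do.call(rbind, strsplit(as.character(alignment), ""))
  if (!is.null(region)) {
    if (length(region) != 2L || region[1] > region[2] ||
        region[1] < 1L || region[2] > ncol(m))
      stop("empty or out-of-range region")
    m <- m[, region[1]:region[2], drop = FALSE]
  }
  aln <- AAStringSet(apply(m, 1, paste, collapse = ""))
  prof <- conservationProfile(aln)
  conserved <- prof$identity >= invariantThreshold &
    prof$occupancy >= minOccupancy
  if (!any(conserved)) return("")
  first <- which(conserved)[1]
  last <- which(conserved)[sum(conserved)]
  toks <- character(0)
  j <- first
  while (j <= last) {
    if (conserved[j]) {
      toks <- c(toks, prof$modal[j])
      j <- j + 1L
    } else {
      runEnd <- j
      while (runEnd < last && !conserved[runEnd + 1L]) runEnd <- runEnd + 1L
      counts <- rowSums(m[, j:runEnd, drop = FALSE] != "-")
      lo <- min(counts); hi <- max(counts)
      if (hi > 0L)
        toks <- c(toks, if (lo == hi) paste0("X", lo)
                  else paste0("X", lo, "-", hi))
      j <- runEnd + 1L
    }
  }
  paste(toks, collapse = "-")
}
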