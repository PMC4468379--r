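# Per-protein architecture calling: compose grammar scans into CHCH /
# tandem-CCCH / ANK / extra-Cys / signature calls and the family filter.

# Ankyrin-repeat consensus (33 residues; x = unspecified). A window is a hit
# when at least `minIdentity` of the specified positions match.
.ANK_CONSENSUS <- "xGxTPLHLAAxxGHxxVVxLLLxxGAxVNAxxx"

.leftmost <- function(matches) {
  if (nrow(matches) == 0L) NULL else matches[1L, , drop = FALSE]
}

.spacerClass <- function(s1) {
  if (is.na(s1)) return(NA_character_)
  if (s1 %in% c(7L, 8L)) "canonical_7_8"
  else if (s1 == 9L) "nine"
  else if (s1 == 5L) "five"
  else if (s1 >= 10L && s1 <= 20L) "long_10_20"
  else "other"
}

#' Check for the subgroup-diagnostic extra cysteine
#'
#' Tests whether the residue a fixed offset upstream of the first CHCH
#' cysteine is itself a cysteine. Most AtTZF1-2-3-like proteins carry this
#' additional Cys 12 residues before the first Cys of the CHCH motif.
#'
#' @param seq protein sequence.
#' @param chchFirstCys 1-based position of the first CHCH cysteine.
#' @param offset upstream offset (default 12).
#' @return logical; `FALSE` with a warning when the position falls outside
#'   the sequence.
#' @export
checkExtraCys <- function(seq, chchFirstCys, offset = 12L) {
  chars <- .seqToChars(seq)
  p <- chchFirstCys - offset
  if (p < 1L) {
    warning("extra-Cys position ", p, " out of range; reporting FALSE")
    return(FALSE)
  }
  chars[p] == "C"
}

#' Count ankyrin repeats
#'
#' `annotation_table` mode counts rows labelled `ANK` for the protein in a
#' domain-annotation table (columns `protein_id`, `domain`, `start`, `end`).
#' `builtin_consensus` mode slides a 33-residue ankyrin consensus along the
#' sequence and counts leftmost-greedy non-overlapping windows matching at
#' least `minIdentity` of the specified consensus positions.
#'
#' @param seq protein sequence.
#' @param proteinId id used to look up annotation rows.
#' @param source `"annotation_table"` or `"builtin_consensus"`.
#' @param ankTable annotation data.frame (required for table mode).
#' @param minIdentity fraction of specified consensus positions that must
#'   match (default 0.5).
#' @return integer repeat count.
#' @export
detectAnk <- function(seq, proteinId = NA_character_,
                      source = c("annotation_table", "builtin_consensus"),
                      ankTable = NULL, minIdentity = 0.5) {
  source <- match.arg(source)
  if (source == "annotation_table") {
    if (is.null(ankTable)) stop("annotation_table mode requires 'ankTable'")
    need <- c("protein_id", "domain")
    if (!all(need %in% names(ankTable)))
      stop("ankTable must have columns protein_id, domain")
    return(sum(ankTable$protein_id == proteinId &
                 toupper(ankTable$domain) == "ANK"))
  }
  chars <- .seqToChars(seq)
  cons <- strsplit(.ANK_CONSENSUS, "")[[1]]
  spec <- which(cons != "x")
  w <- length(cons)
  n <- length(chars)
  if (n < w) return(0L)
  starts <- seq_len(n - w + 1L)
  # vectorized window scoring over the specified consensus positions
  matchCount <- integer(length(starts))
  for (k in spec)
    matchCount <- matchCount + (chars[starts + k - 1L] == cons[k])
  hit <- matchCount / length(spec) >= minIdentity
  count <- 0L; i <- 1L
  while (i <= length(starts)) {
    if (hit[i]) { count <- count + 1L; i <- i + w } else i <- i + 1L
  }
  count
}

#' Scan for the full RR-TZF family signature
#'
#' Leftmost match of the family signature
#' `KX3CX5HX4CX3HX6RRX6YX4CX7-8CX5CX3HX2FEX3HPX7CX5CX4CFFAH`, spanning the
#' CHCH motif and both CCCH domains with their conserved inter-domain
#' residues. A signature hit is strictly stronger than the component filter.
#'
#' @param seq protein sequence.
#' @param grammars grammar list (default [builtinGrammars()]).
#' @return one-row match data.frame (see [scanMotif()]) or `NULL`.
#' @export
signatureScan <- function(seq, grammars = builtinGrammars()) {
  .leftmost(scanMotif(seq, grammars$SIGNATURE))
}

#' Call the RR-TZF domain architecture of a protein
#'
#' Components are selected N-terminus to C-terminus, leftmost first: the
#' CHCH motif, then the first CCCH domain (generalized spacing grammar)
#' starting after the CHCH, then the second CCCH domain (canonical or one of
#' the two variant grammars) starting after the first. A protein is called
#' an RR-TZF (`is_rr_tzf`) when all three components are present
#' simultaneously. The realized first-domain spacer is classified
#' (`canonical_7_8`, `nine`, `five`, `long_10_20`, `other`), the
#' CCCH1-to-CCCH2 linker is checked against `linkerRange`, ankyrin repeats
#' are counted, the upstream extra cysteine is flagged, and the full family
#' signature is scanned.
#'
#' @param proteins `AAStringSet` (or single sequence).
#' @param grammars grammar list (default [builtinGrammars()]).
#' @param linkerRange inclusive bounds on the residues between the last
#'   CCCH1 histidine and the first CCCH2 cysteine; the default (10, 25)
#'   brackets the 16-residue linker fixed by the family signature.
#' @param extraCysOffset upstream offset for [checkExtraCys()].
#' @param ankSource,ankTable,ankMinIdentity see [detectAnk()]; annotation
#'   table mode is used automatically when `ankTable` is supplied.
#' @return data.frame with one row per protein: component coordinates,
#'   `spacer1_length`, `spacer_class`, `ccch2_variant`, `linker_length`,
#'   `tandem_ok`, `ank_count`, `extra_cys`, `signature_start`, `atypical_ccch`
#'   and `is_rr_tzf`. Absent components are `NA`.
#' @export
callArchitecture <- function(proteins, grammars = builtinGrammars(),
                             linkerRange = c(10L, 25L),
                             extraCysOffset = 12L,
                             ankSource = c("builtin_consensus",
                                           "annotation_table"),
                             ankTable = NULL, ankMinIdentity = 0.5) {
  ankSource <- match.arg(ankSource)
  if (!is.null(ankTable)) ankSource <- "annotation_table"
  if (!is(proteins, "XStringSet")) {
    proteins <- AAStringSet(setNames(as.character(proteins),
                                     if (is.null(names(proteins)))
                                       "seq1" else names(proteins)))
  }
  rows <- lapply(seq_along(proteins), function(i) {
    id <- names(proteins)[i]
    s <- as.character(proteins[[i]])
    chch <- .leftmost(scanMotif(s, grammars$CHCH))
    from1 <- if (is.null(chch)) 0L else chch$end
    cc1All <- scanMotif(s, grammars$CCCH1_general)
    ccch1 <- .leftmost(cc1All[cc1All$start > from1, , drop = FALSE])
    from2 <- if (is.null(ccch1)) from1 else ccch1$end
    cand2 <- do.call(rbind, lapply(
      c("CCCH2", "CCCH2_variant_a", "CCCH2_variant_b"), function(g) {
        m <- scanMotif(s, grammars[[g]])
        m <- m[m$start > from2, , drop = FALSE]
        if (nrow(m)) cbind(m[1L, , drop = FALSE], variant = g) else NULL
      }))
    ccch2 <- NULL
    if (!is.null(cand2) && nrow(cand2)) {
      # leftmost across grammars; canonical wins ties (listed first)
      cand2 <- cand2[order(cand2$start, cand2$end), , drop = FALSE]
      ccch2 <- cand2[1L, , drop = FALSE]
    }
    spacer1 <- if (is.null(ccch1)) NA_integer_ else {
      a <- ccch1$anchors[[1]]
      a[2] - a[1] - 1L
    }
    linker <- if (is.null(ccch1) || is.null(ccch2)) NA_integer_ else
      ccch2$start - ccch1$end - 1L
    tandemOk <- !is.na(linker) && linker >= linkerRange[1] &&
      linker <= linkerRange[2]
    ank <- detectAnk(s, proteinId = id, source = ankSource,
                     ankTable = ankTable, minIdentity = ankMinIdentity)
    extraCys <- if (is.null(chch)) FALSE else
      checkExtraCys(s, chch$anchors[[1]][1], offset = extraCysOffset)
    sig <- signatureScan(s, grammars)
    atyp <- .leftmost(scanMotif(s, grammars$CCCH_atypical))
    data.frame(
      protein_id = id,
      chch_start = if (is.null(chch)) NA_integer_ else chch$start,
      chch_end = if (is.null(chch)) NA_integer_ else chch$end,
      ccch1_start = if (is.null(ccch1)) NA_integer_ else ccch1$start,
      ccch1_end = if (is.null(ccch1)) NA_integer_ else ccch1$end,
      spacer1_length = spacer1,
      spacer_class = .spacerClass(spacer1),
      ccch2_start = if (is.null(ccch2)) NA_integer_ else ccch2$start,
      ccch2_end = if (is.null(ccch2)) NA_integer_ else ccch2$end,
      ccch2_variant = if (is.null(ccch2)) NA_character_ else
        switch(ccch2$variant, CCCH2 = "canonical",
               CCCH2_variant_a = "variant_a", CCCH2_variant_b = "variant_b"),
      linker_length = linker,
      tandem_ok = tandemOk,
      ank_count = ank,
      extra_cys = extraCys,
      signature_start = if (is.null(sig)) NA_integer_ else sig$start,
      signature_end = if (is.null(sig)) NA_integer_ else sig$end,
      atypical_ccch = !is.null(atyp),
      is_rr_tzf = !is.null(chch) && !is.null(ccch1) && !is.null(ccch2),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split an architecture table into accepted and excluded reports
#'
#' Proteins that carry at least one RR-TZF component but fail the
#' simultaneous-presence filter (e.g. high-similarity candidates missing the
#' CHCH motif or one CCCH domain) are collected separately, mirroring how
#' near-miss candidates are reported apart from the family proper.
#'
#' @param arch output of [callArchitecture()].
#' @return list with `accepted` (is_rr_tzf rows), `excluded` (partial
#'   architectures) and `blank` (no component at all).
#' @export
excludedReport <- function(arch) {
  hasAny <- !is.na(arch$chch_start) | !is.na(arch$ccch1_start) |
    !is.na(arch$ccch2_start)
  list(accepted = arch[arch$is_rr_tzf, , drop = FALSE],
       excluded = arch[!arch$is_rr_tzf & hasAny, , drop = FALSE],
       blank = arch[!hasAny, , drop = FALSE])
}
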