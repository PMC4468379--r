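# Structure-then-homology classification into RR-TZF groups I-V and the
# AtTZF1-2-3-like (IIa) / AtTZF4-5-like (IIb) subgroups.

# Conserved short motifs diagnostic for the group-II subfamilies. Positions
# quoted in the source alignments are not enforced; patterns are scanned
# anywhere in the protein.
.DIAGNOSTIC_MOTIFS <- c(
  "LX[R/Q]YLP"         = "LX[R/Q]YLP",
  "[L/I]EEXPPMERVESGR" = "[L/I]EEXPPMERVESGR",
  "VXIPP"              = "VXIPP",
  "SPPSESPPLSP"        = "SPPSESPPLSP",
  "NDVVASL"            = "NDVVASL",
  "DVGWVSDLL"          = "DVGWVSDLL",
  "RYLP"               = "RYLP",
  "RKLL"               = "RKLL",
  "CCLFC"              = "CCLFC")

.checkReferenceSet <- function(refs) {
  if (!is(refs, "XStringSet") || length(refs) == 0L)
    stop("reference set must be a non-empty AAStringSet")
  mc <- mcols(refs)
  if (is.null(mc$group))
    stop("reference set needs mcols(refs)$group labels (I..V)")
  if (is.null(mc$subgroup)) mc$subgroup <- NA_character_
  bad <- which(!is.na(mc$subgroup) & mc$subgroup != "none" &
                 mc$group != "II")
  if (length(bad)) stop("subgroup labels only apply to group II exemplars")
  if (anyDuplicated(names(refs))) stop("duplicate exemplar ids")
  invisible(refs)
}

.bestReference <- function(seq, refs) {
  ids <- names(refs)
  sims <- vapply(seq_along(refs), function(k)
    pairIdentity(seq, as.character(refs[[k]])), numeric(1))
  # equal best similarity: lexicographically smallest exemplar id
  ord <- order(-sims, ids)
  list(id = ids[ord[1]], similarity = sims[ord[1]], all = setNames(sims, ids))
}

#' Assign group-II subgroups (AtTZF1-2-3-like vs AtTZF4-5-like)
#'
#' Two-step procedure. Structure step: proteins with ankyrin repeats, a
#' non-canonical first-domain spacer (anything but 7-8), or a variant second
#' CCCH domain are excluded (`basis = "structure_rule"`, subgroup `none`).
#' Homology step: the remaining proteins are compared by global-alignment
#' percent identity against the group-II exemplars; below `minSimilarity`
#' percent the protein stays `unassigned`, otherwise it inherits the
#' subgroup of its best exemplar.
#'
#' @param proteins `AAStringSet` of RR-TZF proteins.
#' @param arch architecture table from [callArchitecture()] (same ids).
#' @param refs labelled exemplar `AAStringSet`; `mcols(refs)$group`,
#'   `mcols(refs)$subgroup` (see [syntheticReferenceSet()]).
#' @param minSimilarity percent identity floor (default 23).
#' @return data.frame: `protein_id`, `group`, `subgroup`, `best_ref_id`,
#'   `best_similarity`, `basis`.
#' @export
assignSubgroup <- function(proteins, arch, refs, minSimilarity = 23) {
  .checkReferenceSet(refs)
  refsII <- refs[mcols(refs)$group == "II"]
  if (length(refsII) == 0L) stop("no group II exemplars in reference set")
  rows <- lapply(seq_along(proteins), function(i) {
    id <- names(proteins)[i]
    a <- arch[arch$protein_id == id, , drop = FALSE]
    if (nrow(a) != 1L) stop("no architecture row for ", id)
    base <- data.frame(protein_id = id, group = NA_character_,
                       subgroup = "none", best_ref_id = NA_character_,
                       best_similarity = NA_real_, basis = "structure_rule",
                       stringsAsFactors = FALSE)
    if (!isTRUE(a$is_rr_tzf)) return(base)
    structOk <- a$ank_count == 0L &&
      identical(a$spacer_class, "canonical_7_8") &&
      identical(a$ccch2_variant, "canonical")
    if (!structOk) return(base)
    best <- .bestReference(as.character(proteins[[i]]), refsII)
    base$best_ref_id <- best$id
    base$best_similarity <- best$similarity
    base$basis <- "nearest_reference"
    if (best$similarity < minSimilarity) {
      base$group <- "unassigned"; base$subgroup <- "none"
    } else {
      base$group <- "II"
      base$subgroup <- mcols(refsII)$subgroup[names(refsII) == best$id]
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign RR-TZF groups I-V
#'
#' Rule order: proteins carrying ankyrin repeats are group I by definition;
#' everything else goes to the group of its nearest exemplar by pairwise
#' global-alignment identity. A `long_10_20` first-domain spacer is recorded
#' as supporting evidence for group V in the `evidence` column (monocot
#' proteins with enlarged first spacings cluster there), but the homology
#' call decides.
#'
#' @inheritParams assignSubgroup
#' @return data.frame: `protein_id`, `group`, `best_ref_id`,
#'   `best_similarity`, `basis`, `evidence`.
#' @export
assignGroup <- function(proteins, arch, refs) {
  .checkReferenceSet(refs)
  rows <- lapply(seq_along(proteins), function(i) {
    id <- names(proteins)[i]
    a <- arch[arch$protein_id == id, , drop = FALSE]
    if (nrow(a) != 1L) stop("no architecture row for ", id)
    ev <- if (identical(a$spacer_class, "long_10_20"))
      "long_spacer1_supports_V" else ""
    if (a$ank_count > 0L) {
      return(data.frame(protein_id = id, group = "I",
                        best_ref_id = NA_character_,
                        best_similarity = NA_real_, basis = "structure_rule",
                        evidence = "ANK_repeats", stringsAsFactors = FALSE))
    }
    best <- .bestReference(as.character(proteins[[i]]), refs)
    grp <- mcols(refs)$group[names(refs) == best$id]
    data.frame(protein_id = id, group = grp, best_ref_id = best$id,
               best_similarity = best$similarity,
               basis = "nearest_reference", evidence = ev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a protein for the diagnostic conserved motifs
#'
#' Compiles each bundled short motif (brackets = alternatives, `X` =
#' one-residue wildcard) and reports which are present anywhere in the
#' protein.
#'
#' @param seq protein sequence.
#' @return character vector of present motif names (empty when none).
#' @export
scanDiagnosticMotifs <- function(seq) {
  hits <- vapply(names(.DIAGNOSTIC_MOTIFS), function(nm) {
    pat <- .compactToPattern(.DIAGNOSTIC_MOTIFS[[nm]], nm)
    nrow(scanMotif(seq, pat)) > 0L
  }, logical(1))
  names(hits)[hits]
}
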