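#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Spacing-grammar motif pattern
#'
#' A `MotifPattern` is an ordered list of elements, each either an anchor
#' (a set of admissible residues, e.g. `C` or `[RQ]`) or a bounded wildcard
#' spacer (`X3`, `X7-8`, `X(5,20)`). Patterns of this form describe zinc-finger
#' domain structures such as `C-X7-8-C-X5-C-X3-H`, where the cysteine and
#' histidine anchors coordinate the zinc ion and the spacers are free.
#'
#' @slot name single string naming the pattern.
#' @slot elements list of elements; each is a list with `type = "anchor"`
#'   (field `residues`, a character vector of single letters) or
#'   `type = "spacer"` (integer fields `min`, `max`).
#'
#' @seealso [parsePattern()], [scanMotif()], [builtinGrammars()]
#' @export
setClass("MotifPattern",
  representation(name = "character", elements = "list"))

setValidity("MotifPattern", function(object) {
  el <- object@elements
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (length(el) == 0L) return("pattern has no elements")
  types <- vapply(el, function(e) e$type, character(1))
  if (!all(types %in% c("anchor", "spacer")))
    return("elements must be anchors or spacers")
  if (types[1L] != "anchor" || types[length(types)] != "anchor")
    return("pattern must start and end with an anchor")
  for (e in el) {
    if (e$type == "anchor") {
      if (length(e$residues) < 1L || !all(grepl("^[A-WYZ]$", e$residues)))
        return("anchor residues must be single amino-acid letters (not X)")
    } else {
      if (e$min < 0L || e$max < e$min)
        return("spacer bounds must satisfy 0 <= min <= max")
    }
  }
  TRUE
})

setMethod("show", "MotifPattern", function(object) {
  cat("MotifPattern '", object@name, "': ", renderPattern(object), "\n",
      sep = "")
  na <- sum(vapply(object@elements, function(e) e$type == "anchor", logical(1)))
  cat("  ", na, " anchors, ", length(object@elements) - na, " spacers\n",
      sep = "")
})

.anchor <- function(residues) list(type = "anchor", residues = residues)
.spacer <- function(min, max = min)
  list(type = "spacer", min = as.integer(min), max = as.integer(max))

#' Parse a spacing-grammar pattern expression
#'
#' Accepts the dash-separated mini-language used throughout the package:
#' anchors are residue letters or bracketed alternative sets (`[RQ]` or
#' `[R/Q]`); spacers are `X3` (fixed), `X7-8` or `X(7,8)` (bounded range).
#' A bare `X` is a one-residue wildcard spacer.
#'
#' @param text pattern expression, e.g. `"C-X7-8-C-X5-C-X3-H"`.
#' @param name optional pattern name (defaults to the expression itself).
#' @return a [MotifPattern-class] object.
#' @examples
#' parsePattern("C-X(7,8)-C-X5-C-X3-H", "CCCH1_canonical")
#' @export
parsePattern <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\s+", "", text)
  if (!nzchar(text)) stop("empty pattern expression")
  toks <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(toks))) stop("empty element in pattern: ", text)
  # re-join range spacers split by the dash: "X7-8" -> tokens "X7","8"
  merged <- character(0)
  for (tk in toks) {
    n <- length(merged)
    if (n > 0L && grepl("^[0-9]+$", tk) && grepl("^X[0-9]+$", merged[n])) {
      merged[n] <- paste0(merged[n], "-", tk)
    } else {
      merged <- c(merged, tk)
    }
  }
  elements <- lapply(merged, function(tk) {
    if (grepl("^X$", tk)) return(.spacer(1L))
    if (grepl("^X[0-9]+$", tk)) return(.spacer(as.integer(sub("X", "", tk))))
    if (grepl("^X[0-9]+-[0-9]+$", tk)) {
      b <- as.integer(strsplit(sub("X", "", tk), "-")[[1]])
      return(.spacer(b[1], b[2]))
    }
    if (grepl("^X\\([0-9]+,[0-9]+\\)$", tk)) {
      b <- as.integer(strsplit(gsub("[X()]", "", tk), ",")[[1]])
      return(.spacer(b[1], b[2]))
    }
    if (grepl("^[A-WYZ]$", tk)) return(.anchor(tk))
    if (grepl("^\\[[A-WYZ/]+\\]$", tk)) {
      res <- strsplit(gsub("[][/]", "", tk), "")[[1]]
      return(.anchor(unique(res)))
    }
    stop("unparseable pattern element '", tk, "' in: ", text)
  })
  new("MotifPattern", name = name, elements = elements)
}

#' Render a pattern back to its expression
#'
#' `parsePattern(renderPattern(p))` reproduces `p` element-for-element.
#'
#' @param pattern a [MotifPattern-class].
#' @return single string in the mini-language.
#' @export
renderPattern <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  paste(vapply(pattern@elements, function(e) {
    if (e$type == "anchor") {
      if (length(e$residues) == 1L) e$residues
      else paste0("[", paste(e$residues, collapse = ""), "]")
    } else if (e$min == e$max) paste0("X", e$min)
    else paste0("X", e$min, "-", e$max)
  }, character(1)), collapse = "-")
}

# Compile a compact motif literal such as "LX[R/Q]YLP" or "RYLP" into a
# MotifPattern (X = one-residue wildcard; brackets = alternatives).
.compactToPattern <- function(text, name = text) {
  chars <- strsplit(gsub("\\s+", "", text), "")[[1]]
  toks <- character(0); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unclosed bracket in motif: ", text)
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "X") {
      toks <- c(toks, "X"); i <- i + 1L
    } else {
      toks <- c(toks, ch); i <- i + 1L
    }
  }
  parsePattern(paste(toks, collapse = "-"), name)
}

#' Built-in RR-TZF domain grammars
#'
#' Loads the bundled pattern set covering the RR-TZF domain vocabulary:
#' the canonical and generalized first CCCH domain, the second CCCH domain
#' and its two variants, the CHCH motif of the arginine-rich region, the
#' full family signature, the atypical overlapping CCCH arrangement, and
#' the ankyrin-repeat consensus used by the built-in ANK detector.
#'
#' @param file path to a grammar file (two tab-separated columns: name,
#'   pattern expression; `#` comments allowed). Defaults to the bundled set.
#' @return named list of [MotifPattern-class] objects.
#' @export
builtinGrammars <- function(file = system.file("extdata", "rr_tzf_grammars.txt",
                                               package = "rrtzf")) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t")
  pats <- lapply(parts, function(p) parsePattern(p[2], name = p[1]))
  names(pats) <- vapply(parts, `[[`, character(1), 1)
  pats
}

.seqToChars <- function(seq) {
  if (is(seq, "XString")) seq <- as.character(seq)
  if (is(seq, "XStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- as.character(seq[[1]])
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("-", seq, fixed = TRUE))
    stop("gapped sequence passed to the motif scanner; degap it first")
  strsplit(seq, "")[[1]]
}

#' Scan a protein with a spacing-grammar pattern
#'
#' Enumerates anchor placements of `pattern` in `seq`. With `mode = "all"`
#' every distinct placement of the anchors satisfying the spacer bounds is
#' returned; `mode = "nonoverlapping"` keeps a leftmost-greedy
#' non-overlapping subset (earliest start; among equal starts, the shortest
#' span). Anchors require the literal residue: an `X` in the subject
#' sequence can sit in a spacer but never satisfies an anchor.
#'
#' @param seq protein sequence (character, `AAString`, or length-1
#'   `AAStringSet`); gaps are rejected.
#' @param pattern a [MotifPattern-class] or a pattern expression string.
#' @param mode `"all"` or `"nonoverlapping"`.
#' @return data.frame with columns `pattern`, `start`, `end` (1-based,
#'   inclusive anchor coordinates) and a list-column `anchors` of named
#'   integer vectors (names = anchor residues matched); rows sorted by
#'   `(start, end)`. Zero rows when there is no match.
#' @examples
#' scanMotif("IDAYSCDHFRMYDFKVRRCARGRSHDWTECPYAH", "C-X5-H-X4-C-X3-H")
#' @export
scanMotif <- function(seq, pattern, mode = c("all", "nonoverlapping")) {
  mode <- match.arg(mode)
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  stopifnot(is(pattern, "MotifPattern"))
  chars <- .seqToChars(seq)
  hits <- .scanChars(chars, pattern@elements)
  out <- .matchFrame(pattern@name, hits, chars)
  if (mode == "nonoverlapping" && nrow(out) > 0L) {
    keep <- logical(nrow(out)); lastEnd <- 0L
    for (i in seq_len(nrow(out))) {
      if (out$start[i] > lastEnd) { keep[i] <- TRUE; lastEnd <- out$end[i] }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Depth-first enumeration of anchor placements. Returns a list of integer
# vectors of anchor positions.
.scanChars <- function(chars, elements) {
  n <- length(chars)
  isAnchor <- vapply(elements, function(e) e$type == "anchor", logical(1))
  anchorIdx <- which(isAnchor)
  res <- list()
  dfs <- function(ei, pos, acc) {
    # ei indexes the next element; pos is the position of the last anchor
    if (ei > length(elements)) { res[[length(res) + 1L]] <<- acc; return() }
    e <- elements[[ei]]
    if (e$type == "anchor") {
      p <- pos + 1L
      if (p <= n && chars[p] %in% e$residues) dfs(ei + 1L, p, c(acc, p))
    } else {
      nxt <- elements[[ei + 1L]]  # validity guarantees an anchor follows
      for (gap in e$min:e$max) {
        p <- pos + gap + 1L
        if (p > n) break
        if (chars[p] %in% nxt$residues) dfs(ei + 2L, p, c(acc, p))
      }
    }
  }
  first <- elements[[1]]
  for (s in which(chars %in% first$residues)) dfs(2L, s, s)
  res
}

.matchFrame <- function(patName, hits, chars) {
  if (length(hits) == 0L) {
    return(data.frame(pattern = character(0), start = integer(0),
                      end = integer(0),
                      anchors = I(list())))
  }
  start <- vapply(hits, function(h) h[1], integer(1))
  end <- vapply(hits, function(h) h[length(h)], integer(1))
  ord <- order(start, end)
  anchors <- lapply(hits[ord], function(h) {
    names(h) <- chars[h]
    h
  })
  data.frame(pattern = patName, start = start[ord], end = end[ord],
             anchors = I(anchors), row.names = NULL)
}
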