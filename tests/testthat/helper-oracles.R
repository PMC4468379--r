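# Independent oracles used across the suite. These deliberately take a
# different algorithmic route from the package implementation.

# Enumerate every anchor placement of a spacing-grammar pattern by looping
# over all spacer-length combinations (each combination fixes the anchor
# offsets, so placements <-> (start, spacer vector) bijectively) and testing
# every start position.
oracleScan <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  el <- pattern@elements
  anchors <- Filter(function(e) e$type == "anchor", el)
  # gap bounds between consecutive anchors (0 for adjacent anchors)
  gaps <- list()
  i <- 1L
  while (i < length(el)) {
    if (el[[i]]$type == "anchor") {
      nxt <- el[[i + 1L]]
      gaps[[length(gaps) + 1L]] <-
        if (nxt$type == "spacer") nxt$min:nxt$max else 0L
      i <- i + if (nxt$type == "spacer") 2L else 1L
    } else i <- i + 1L
  }
  combos <- if (length(gaps)) expand.grid(gaps) else
    data.frame(row.names = 1)
  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    offs <- cumsum(c(0L, as.integer(combos[ci, ]) + 1L))
    for (s in seq_along(chars)) {
      pos <- s + offs
      if (max(pos) > length(chars)) next
      ok <- all(vapply(seq_along(anchors), function(k)
        chars[pos[k]] %in% anchors[[k]]$residues, logical(1)))
      if (ok) hits[[length(hits) + 1L]] <- pos
    }
  }
  if (!length(hits)) {
    out <- data.frame(start = integer(0), end = integer(0))
    out$anchors <- I(list())
    return(out)
  }
  df <- data.frame(start = vapply(hits, `[`, integer(1), 1),
                   end = vapply(hits, function(h) h[length(h)], integer(1)))
  anch <- lapply(hits, identity)
  df$anchors <- I(anch)
  df <- df[order(df$start, df$end), ]
  rownames(df) <- NULL
  df
}

# Exhaustive global-alignment score under a LINEAR gap model (recursion over
# the three edit moves); for tiny sequences only.
oracleAlignScore <- function(a, b, S, gapPer) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    S[substr(a, i, i), substr(b, j, j)])
    if (i > 0) best <- max(best, rec(i - 1, j) - gapPer)
    if (j > 0) best <- max(best, rec(i, j - 1) - gapPer)
    best
  }
  rec(nchar(a), nchar(b))
}

# Random protein under the generator's background composition
randomProteinChars <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- ifelse(aa %in% c("C", "H"), 0.3, 1)
  paste(sample(aa, n, replace = TRUE, prob = w / sum(w)), collapse = "")
}

# Gapped alignment of exact signature instances with chosen first-domain
# spacer lengths (7 or 8); per-row random fillers. Rows with spacer 7 carry
# one gap column inside the variable spacer so all rows share a layout.
buildSignatureAlignment <- function(spacers) {
  filler <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("C", "H"))
  rows <- vapply(spacers, function(s1) {
    f <- function(n) paste(sample(filler, n, replace = TRUE), collapse = "")
    sp1 <- if (s1 == 8L) f(8) else paste0(f(7), "-")
    paste0("K", f(3), "C", f(5), "H", f(4), "C", f(3), "H", f(6), "RR",
           f(6), "Y", f(4), "C", sp1, "C", f(5), "C", f(3), "H", f(2),
           "FE", f(3), "HP", f(7), "C", f(5), "C", f(4), "C", "FFA", "H")
  }, character(1))
  aln <- Biostrings::AAStringSet(rows)
  names(aln) <- paste0("s", seq_along(spacers))
  aln
}

# Random additive distance matrix: random unrooted binary topology with
# positive branch lengths; distances = path lengths.
randomAdditiveMatrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 2))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = cophenetic(tr)[tr$tip.label, tr$tip.label])
}

# Bootstrap support of the internal edges whose bipartition is one of the
# given tip pairs (a pair may appear as a 2-tip clade or its complement).
trueCladeSupports <- function(tree, pairs) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs)
  vapply(pairs, function(pr) {
    for (i in seq_along(parts)) {
      tips <- sort(labs[parts[[i]]])
      comp <- sort(setdiff(labs, tips))
      if (identical(tips, sort(pr)) || identical(comp, sort(pr)))
        return(suppressWarnings(as.numeric(tree$node.label[i])))
    }
    NA_real_
  }, numeric(1))
}

defaultCounts <- function(k = 5L) {
  stats::setNames(rep(k, 7L),
                  c("IIa", "IIa_extra_cys", "IIb", "groupI_ank",
                    "groupV_longspacer", "decoy_broken_spacing",
                    "decoy_random"))
}
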