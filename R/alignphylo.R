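#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @importFrom stats setNames hclust as.dist cophenetic
#' @importFrom ape nj write.tree read.tree prop.clades prop.part
NULL

.BLOSUM62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment under an affine gap model (Biostrings
#' engine). Identity is the number of identical aligned pairs divided by the
#' number of alignment columns holding at least one residue, as a percent.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @param substitutionMatrix scoring matrix (default BLOSUM62).
#' @param gapOpening,gapExtend affine gap penalties.
#' @return list with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   and `identity` (percent).
#' @export
globalAlign <- function(a, b, substitutionMatrix = .BLOSUM62,
                        gapOpening = 10, gapExtend = 0.5) {
  a <- paste(.seqToChars(a), collapse = "")
  b <- paste(.seqToChars(b), collapse = "")
  if (nchar(a) == 0L || nchar(b) == 0L) {
    gaps <- function(k) paste(rep("-", k), collapse = "")
    return(list(aligned_a = if (nchar(a)) a else gaps(nchar(b)),
                aligned_b = if (nchar(b)) b else gaps(nchar(a)),
                score = NA_real_, identity = 0))
  }
  pa <- pairwiseAlignment(a, b, type = "global",
                          substitutionMatrix = substitutionMatrix,
                          gapOpening = gapOpening, gapExtension = gapExtend)
  pat <- as.character(alignedPattern(pa))
  sub <- as.character(alignedSubject(pa))
  pc <- strsplit(pat, "")[[1]]
  sc <- strsplit(sub, "")[[1]]
  occupied <- pc != "-" | sc != "-"
  ident <- 100 * sum(pc == sc & pc != "-") / sum(occupied)
  list(aligned_a = pat, aligned_b = sub, score = unname(pa@score),
       identity = ident)
}

#' Percent-identity of one pair (convenience wrapper)
#' @inheritParams globalAlign
#' @return percent identity in \[0, 100\].
#' @export
pairIdentity <- function(a, b, ...) globalAlign(a, b, ...)$identity

#' Pairwise similarity matrix from a multiple alignment
#'
#' `similarity(i, j) = 100 * (identical residue pairs) / (columns where at
#' least one of i, j holds a residue)`; symmetric with a diagonal of 100.
#' This is the convention used when similarities are read off the distance
#' matrix of a multi-alignment.
#'
#' @param alignment gapped `AAStringSet` (>= 2 rows).
#' @return numeric matrix with row/col names = sequence ids.
#' @export
similarityMatrix <- function(alignment) {
  if (length(alignment) < 2L) stop("need at least 2 aligned sequences")
  m <- do.call(rbind, strsplit(as.character(alignment), ""))
  rownames(m) <- names(alignment)
  if (any(rowSums(m != "-") == 0L))
    stop("all-gap row(s): ",
         paste(rownames(m)[rowSums(m != "-") == 0L], collapse = ", "))
  n <- nrow(m)
  sim <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- m[i, ]; rj <- m[j, ]
    occ <- ri != "-" | rj != "-"
    sim[i, j] <- sim[j, i] <- 100 * sum(ri == rj & ri != "-") / sum(occ)
  }
  sim
}

#' p-distance matrix from a multiple alignment
#'
#' `d(i, j) = 1 - similarity(i, j) / 100` under the [similarityMatrix()]
#' convention.
#'
#' @param alignment gapped `AAStringSet`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(alignment) 1 - similarityMatrix(alignment) / 100

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (ape engine). Negative branch-length estimates
#' are clamped to zero with a warning, the standard practice for NJ on
#' non-additive data.
#'
#' @param d symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return unrooted `phylo` tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) >= 3L, !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  tree <- nj(d)
  if (any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap supports for an alignment-based tree
#'
#' Alignment columns are resampled with replacement; the tree builder is
#' applied to each replicate and the support of each internal edge of the
#' full-data tree is the percentage of replicate trees containing the
#' corresponding bipartition. Seeded, hence reproducible.
#'
#' @param alignment gapped `AAStringSet`.
#' @param replicates number of bootstrap replicates (0 = no supports).
#' @param seed RNG seed.
#' @param distFun alignment -> distance matrix (default [pDistanceMatrix()]).
#' @param builder distance matrix -> `phylo` (default [njTree()]).
#' @return `phylo` with `node.label` holding integer percent supports
#'   (root label empty).
#' @export
bootstrapSupport <- function(alignment, replicates = 1000L, seed = 1L,
                             distFun = pDistanceMatrix, builder = njTree) {
  base <- suppressWarnings(builder(distFun(alignment)))
  if (replicates == 0L) return(base)
  m <- do.call(rbind, strsplit(as.character(alignment), ""))
  rownames(m) <- names(alignment)
  reps <- .withSeed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      rs <- AAStringSet(apply(m[, cols, drop = FALSE], 1, paste,
                              collapse = ""))
      names(rs) <- rownames(m)
      suppressWarnings(builder(distFun(rs)))
    })
  })
  counts <- prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / replicates)
  supp[1] <- NA  # root of the unrooted representation carries no bipartition
  base$node.label <- ifelse(is.na(supp), "", as.character(supp))
  base
}

#' Hide low bootstrap supports
#'
#' Blanks node labels below `min` percent, the usual display convention for
#' published NJ trees.
#'
#' @param tree `phylo` with percent supports in `node.label`.
#' @param min threshold (default 50).
#' @return tree with low supports blanked.
#' @export
filterSupports <- function(tree, min = 50) {
  if (is.null(tree$node.label)) return(tree)
  v <- suppressWarnings(as.numeric(tree$node.label))
  tree$node.label[!is.na(v) & v < min] <- ""
  tree
}

#' Write a tree in Newick format
#' @param tree `phylo`.
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  write.tree(tree, file = path)
  invisible(path)
}

# --- progressive multiple alignment -----------------------------------------

.profileOf <- function(gapped) {
  # 20 x L residue-frequency matrix (gaps excluded from frequencies) plus
  # occupancy vector
  aa <- names(.AA_AVG_MASS)
  m <- do.call(rbind, strsplit(gapped, ""))
  L <- ncol(m)
  f <- matrix(0, length(aa), L, dimnames = list(aa, NULL))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col != "-" & col %in% aa]
    if (length(col)) f[, j] <- tabulate(factor(col, levels = aa),
                                        nbins = length(aa)) / length(col)
  }
  list(freq = f, rows = gapped)
}

.alignProfiles <- function(p1, p2, S, gap = -4) {
  F1 <- p1$freq; F2 <- p2$freq
  aa <- rownames(F1)
  M <- t(F1) %*% S[aa, aa] %*% F2
  n1 <- ncol(F1); n2 <- ncol(F2)
  D <- matrix(0, n1 + 1L, n2 + 1L)
  D[1L, ] <- gap * (0:n2)
  D[, 1L] <- gap * (0:n1)
  P <- matrix(0L, n1 + 1L, n2 + 1L)  # 1 diag, 2 up, 3 left
  P[1L, -1L] <- 3L; P[-1L, 1L] <- 2L
  for (i in seq_len(n1)) {
    Dprev <- D[i, ]
    drow <- D[i + 1L, ]
    for (j in seq_len(n2)) {
      sDiag <- Dprev[j] + M[i, j]
      sUp <- Dprev[j + 1L] + gap
      sLeft <- drow[j] + gap
      best <- max(sDiag, sUp, sLeft)
      drow[j + 1L] <- best
      P[i + 1L, j + 1L] <- if (best == sDiag) 1L else if (best == sUp) 2L
        else 3L
    }
    D[i + 1L, ] <- drow
  }
  i <- n1; j <- n2
  ops <- integer(0)
  while (i > 0L || j > 0L) {
    op <- P[i + 1L, j + 1L]
    ops <- c(op, ops)
    if (op == 1L) { i <- i - 1L; j <- j - 1L }
    else if (op == 2L) i <- i - 1L
    else j <- j - 1L
  }
  expand <- function(rows, keepOp) {
    chs <- strsplit(rows, "")
    vapply(chs, function(ch) {
      out <- character(length(ops)); k <- 0L
      for (t in seq_along(ops)) {
        if (ops[t] %in% keepOp) { k <- k + 1L; out[t] <- ch[k] }
        else out[t] <- "-"
      }
      paste(out, collapse = "")
    }, character(1))
  }
  c(expand(p1$rows, c(1L, 2L)), expand(p2$rows, c(1L, 3L)))
}

#' Progressive multiple sequence alignment
#'
#' A deterministic built-in progressive aligner: pairwise global-alignment
#' distances feed an average-linkage guide tree whose merge order drives
#' profile-profile Needleman-Wunsch alignment (sum-of-pairs BLOSUM62 column
#' scores, linear gap penalty). Intended to make the pipeline self-contained
#' on modest sequence sets; a dedicated aligner will outperform it on large
#' or highly divergent inputs.
#'
#' @param seqs ungapped `AAStringSet` (>= 2 sequences).
#' @param gap linear gap penalty per column (default -4).
#' @return gapped `AAStringSet` in the input order.
#' @export
progressiveMsa <- function(seqs, gap = -4) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  ids <- names(seqs)
  raw <- as.character(seqs)
  if (n == 2L) {
    al <- globalAlign(raw[1], raw[2])
    out <- AAStringSet(c(al$aligned_a, al$aligned_b))
    names(out) <- ids
    return(out)
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- 1 - pairIdentity(raw[i], raw[j]) / 100
  hc <- hclust(as.dist(d), method = "average")
  profiles <- list()
  clusterRows <- list()
  getLeaf <- function(k) list(p = .profileOf(setNames(raw[k], ids[k])),
                              ids = ids[k])
  nodes <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) getLeaf(-v) else nodes[[v]]
    a <- pick(hc$merge[s, 1]); b <- pick(hc$merge[s, 2])
    merged <- .alignProfiles(a$p, b$p, .BLOSUM62, gap = gap)
    names(merged) <- c(a$ids, b$ids)
    nodes[[s]] <- list(p = .profileOf(merged), ids = names(merged))
  }
  finalRows <- nodes[[nrow(hc$merge)]]$p$rows
  out <- AAStringSet(finalRows[ids])
  names(out) <- ids
  out
}
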