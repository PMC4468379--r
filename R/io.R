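#' @importFrom Biostrings readBStringSet AAStringSet DNAStringSet
#'   writeXStringSet width
NULL

.AA_LETTERS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
.DNA_LETTERS <- c("A", "C", "G", "T", "N")

.checkAlphabet <- function(x, alphabet) {
  letters <- if (alphabet == "protein") .AA_LETTERS else .DNA_LETTERS
  bad <- which(vapply(as.character(x), function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    !all(ch %in% letters)
  }, logical(1)))
  if (length(bad))
    stop("record(s) ", paste(names(x)[bad], collapse = ", "),
         " contain symbols outside the ", alphabet, " alphabet")
  invisible(x)
}

#' Read a FASTA file of protein or DNA sequences
#'
#' Records are returned as an `AAStringSet` (or `DNAStringSet`). Names are
#' the first whitespace-delimited header token; the full header is kept in
#' `mcols(x)$description`. Residues are uppercased and validated against the
#' alphabet (ambiguity codes `X`/`N` allowed).
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"dna"`.
#' @return an `AAStringSet` or `DNAStringSet` with per-record descriptions.
#' @export
readFasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  nonEmpty <- raw[nzchar(trimws(raw))]
  if (length(nonEmpty) && !startsWith(nonEmpty[1], ">"))
    stop("malformed FASTA: first non-empty line (line ",
         which(nzchar(trimws(raw)))[1], ") is not a header")
  set <- readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    out <- if (alphabet == "protein") AAStringSet() else DNAStringSet()
    return(out)
  }
  if (any(width(set) == 0L)) {
    empt <- names(set)[width(set) == 0L]
    stop("empty sequence for record(s): ", paste(empt, collapse = ", "))
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  .checkAlphabet(seqs, alphabet)
  out <- if (alphabet == "protein") AAStringSet(seqs) else DNAStringSet(seqs)
  names(out) <- ids
  mcols(out)$description <- headers
  out
}

#' Write sequences to FASTA (60-column wrapping)
#'
#' Headers are `id description` when a description differing from the id is
#' present in `mcols`.
#'
#' @param x an `XStringSet` with names.
#' @param path output path.
#' @export
writeFasta <- function(x, path) {
  hdr <- names(x)
  desc <- mcols(x)$description
  if (!is.null(desc)) hdr <- ifelse(desc == hdr, hdr, desc)
  y <- x
  names(y) <- hdr
  writeXStringSet(y, path, width = 60L)
  invisible(path)
}

#' Read a multiple alignment
#'
#' Supports gapped FASTA and Clustal dialects. The only accepted gap symbol
#' is `-`; a `.` anywhere in an aligned sequence is rejected with a clear
#' message because Clustal dialects disagree on its meaning. All rows must
#' have the same gapped length.
#'
#' @param path alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return an `AAStringSet` of equal-width gapped rows.
#' @export
readAlignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned-fasta") {
    set <- readBStringSet(path)
    ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
    seqs <- toupper(as.character(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[1], ignore.case = TRUE))
      stop("not a Clustal file (missing CLUSTAL header line): ", path)
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    # drop conservation lines (leading whitespace)
    body <- body[!grepl("^\\s", body)]
    toks <- strsplit(trimws(body), "\\s+")
    toks <- toks[vapply(toks, length, integer(1)) >= 2L]
    ids0 <- vapply(toks, `[[`, character(1), 1)
    frag <- toupper(vapply(toks, `[[`, character(1), 2))
    ids <- unique(ids0)
    seqs <- vapply(ids, function(id)
      paste(frag[ids0 == id], collapse = ""), character(1))
  }
  if (any(grepl(".", seqs, fixed = TRUE)))
    stop("'.' gap symbol found (rows: ",
         paste(ids[grepl(".", seqs, fixed = TRUE)], collapse = ", "),
         "); only '-' is accepted")
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    off <- ids[w != max(w)]
    stop("ragged alignment; offending row(s): ", paste(off, collapse = ", "))
  }
  aln <- AAStringSet(seqs)
  names(aln) <- ids
  aln
}

#' Remove gaps from an alignment
#'
#' @param alignment gapped `AAStringSet`.
#' @return ungapped `AAStringSet` in the same order.
#' @export
degap <- function(alignment) {
  out <- AAStringSet(gsub("-", "", as.character(alignment), fixed = TRUE))
  names(out) <- names(alignment)
  out
}

.readTypedTsv <- function(path, required, numeric_cols, what) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cl in numeric_cols) tab[[cl]] <- as.numeric(tab[[cl]])
  tab[required]
}

#' Read a long-format qPCR Ct table
#'
#' Required columns: `gene`, `group`, `bio_rep`, `tech_rep`, `ct`.
#' Technical replicates are kept as separate rows; averaging happens inside
#' [ddct()].
#'
#' @param path TSV path.
#' @return data.frame with the required columns.
#' @export
readCtTable <- function(path) {
  tab <- .readTypedTsv(path, c("gene", "group", "bio_rep", "tech_rep", "ct"),
                       "ct", "Ct table")
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    stop("Ct values must be positive and finite")
  tab
}

#' Read a germination count table
#'
#' Required columns: `genotype`, `condition`, `rep`, `germinated`, `total`.
#'
#' @param path TSV path.
#' @return data.frame with the required columns.
#' @export
readGerminationTable <- function(path) {
  tab <- .readTypedTsv(path,
                       c("genotype", "condition", "rep", "germinated", "total"),
                       c("germinated", "total"), "germination table")
  if (any(tab$total <= 0)) stop("'total' must be positive")
  if (any(tab$germinated < 0 | tab$germinated > tab$total))
    stop("'germinated' must lie in [0, total]")
  tab
}

#' Write a report data.frame as TSV
#'
#' Deterministic column order (as given), one row per protein/match, no
#' quoting, no row names. List-columns are flattened to comma-separated
#' strings.
#'
#' @param report data.frame.
#' @param path output path.
#' @param meta optional named character vector echoed as `# key: value`
#'   header lines.
#' @export
writeTsvReport <- function(report, path, meta = NULL) {
  flat <- report
  for (cl in names(flat)) {
    if (is.list(flat[[cl]]))
      flat[[cl]] <- vapply(flat[[cl]], function(v)
        paste(v, collapse = ","), character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
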