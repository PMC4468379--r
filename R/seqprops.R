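#' @importFrom Biostrings DNAString translate GENETIC_CODE reverseComplement
NULL

# Average (isotope-abundance weighted) residue masses in Da, ExPASy values.
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_AVG_MASS <- 18.01524

# EMBOSS pKa set used by the charge model.
.PKA <- list(
  Nterm = 8.6, Cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

#' Find the longest open reading frame on the forward strand
#'
#' Scans all three forward frames (optionally both strands) for ATG-to-stop
#' reading frames and returns the longest; ties are broken by the smallest
#' start coordinate. Intronless genes whose genomic and cDNA sequences are
#' identical can be characterized directly this way.
#'
#' @param dna DNA sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`) of length >= 6.
#' @param bothStrands also search the reverse complement (coordinates are
#'   still reported on the forward strand orientation of the hit).
#' @return a list with `found` (logical); when found: `start`, `end`
#'   (1-based inclusive nucleotide coordinates, stop codon included),
#'   `length_nt`, `strand`, and `protein` (character, stop not included).
#'   `found = FALSE` (not an error) when no ORF exists.
#' @examples
#' findLongestOrf("ATGAAATAA")
#' @export
findLongestOrf <- function(dna, bothStrands = FALSE) {
  if (is(dna, "XStringSet")) dna <- as.character(dna[[1]])
  if (is(dna, "XString")) dna <- as.character(dna)
  dna <- toupper(dna)
  if (nchar(dna) < 6L) stop("sequence shorter than 6 nt")
  strands <- if (bothStrands) c("+", "-") else "+"
  best <- NULL
  for (st in strands) {
    s <- if (st == "+") dna else
      as.character(reverseComplement(DNAString(dna)))
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    for (frame in 0:2) {
      starts <- seq(1L + frame, n - 2L, by = 3L)
      codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
      isStart <- codons == "ATG"
      isStop <- codons %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open) && isStart[i]) open <- i
        if (!is.na(open) && isStop[i]) {
          lenNt <- (i - open + 1L) * 3L
          cand <- list(found = TRUE, start = starts[open],
                       end = starts[i] + 2L, length_nt = lenNt, strand = st)
          if (is.null(best) || lenNt > best$length_nt ||
              (lenNt == best$length_nt && cand$start < best$start &&
               st == best$strand))
            best <- cand
          open <- NA_integer_
        }
      }
    }
  }
  if (is.null(best)) return(list(found = FALSE))
  s <- if (best$strand == "+") dna else
    as.character(reverseComplement(DNAString(dna)))
  orfSeq <- substr(s, best$start, best$end)
  best$protein <- translateDna(substr(orfSeq, 1L, nchar(orfSeq) - 3L))
  best
}

#' Translate a DNA frame with the standard genetic code
#'
#' @param dnaFrame in-frame DNA string (length divisible by 3); a trailing
#'   stop codon, if present, is trimmed from the protein. An internal stop
#'   is an error.
#' @return protein string.
#' @export
translateDna <- function(dnaFrame) {
  if (is(dnaFrame, "XString")) dnaFrame <- as.character(dnaFrame)
  dnaFrame <- toupper(dnaFrame)
  if (nchar(dnaFrame) %% 3L != 0L) stop("frame length not divisible by 3")
  aa <- as.character(translate(DNAString(dnaFrame), if.fuzzy.codon = "X"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon at protein position ",
         regexpr("*", aa, fixed = TRUE)[1])
  aa
}

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water, using the ExPASy average
#' atomic-mass table; reported in kDa. Ambiguity codes have no defined mass.
#'
#' @param protein ungapped protein string (no `X`).
#' @param unit `"kDa"` (default) or `"Da"`.
#' @return numeric mass.
#' @examples
#' molecularWeight("G", unit = "Da")  # 75.07
#' @export
molecularWeight <- function(protein, unit = c("kDa", "Da")) {
  unit <- match.arg(unit)
  chars <- .seqToChars(protein)
  if (length(chars) == 0L) stop("empty protein")
  if (any(!chars %in% names(.AA_AVG_MASS)))
    stop("mass undefined for residue(s): ",
         paste(unique(chars[!chars %in% names(.AA_AVG_MASS)]), collapse = ", "))
  da <- sum(.AA_AVG_MASS[chars]) + .WATER_AVG_MASS
  if (unit == "kDa") da / 1000 else da
}

.netCharge <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - .PKA$Nterm)) +
    sum(counts[names(.PKA$positive)] / (1 + 10^(pH - .PKA$positive)),
        na.rm = TRUE)
  neg <- 1 / (1 + 10^(.PKA$Cterm - pH)) +
    sum(counts[names(.PKA$negative)] / (1 + 10^(.PKA$negative - pH)),
        na.rm = TRUE)
  pos - neg
}

#' Isoelectric point by bisection on the net-charge function
#'
#' Henderson-Hasselbalch charges for the termini and ionizable side chains
#' (C, D, E, H, K, R, Y) under the EMBOSS pKa set; the pH at which the net
#' charge crosses zero is located by bisection on \[0, 14\] to a tolerance
#' of 1e-4. pI values are pKa-set dependent, so agreement with other tools
#' is approximate by nature.
#'
#' @param protein ungapped protein string.
#' @return numeric pI with attributes `pka_set` (`"EMBOSS"`) and
#'   `net_charge` (residual charge at the returned pH).
#' @export
isoelectricPoint <- function(protein) {
  chars <- .seqToChars(protein)
  if (length(chars) == 0L) stop("empty protein")
  counts <- table(factor(chars, levels = names(.AA_AVG_MASS)))
  lo <- 0; hi <- 14
  if (.netCharge(counts, lo) < 0 || .netCharge(counts, hi) > 0)
    stop("net charge does not change sign on [0, 14]")
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (.netCharge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  pI <- (lo + hi) / 2
  attr(pI, "pka_set") <- "EMBOSS"
  attr(pI, "net_charge") <- .netCharge(counts, pI)
  pI
}

#' Sequence-property report for a set of sequences
#'
#' For DNA input: length, longest-ORF coordinates and length, encoded
#' protein length, MW (kDa) and pI of the encoded protein. For protein
#' input: length, MW, pI.
#'
#' @param x `DNAStringSet` or `AAStringSet` (see [readFasta()]).
#' @param alphabet `"dna"` or `"protein"`.
#' @return data.frame, one row per record.
#' @export
seqPropsTable <- function(x, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  rows <- lapply(seq_along(x), function(i) {
    s <- as.character(x[[i]])
    id <- names(x)[i]
    if (alphabet == "dna") {
      orf <- findLongestOrf(s)
      if (!orf$found)
        return(data.frame(id = id, length_nt = nchar(s), orf_start = NA,
                          orf_end = NA, orf_length_nt = NA,
                          protein_length = NA, mw_kda = NA, pi = NA))
      prot <- orf$protein
      data.frame(id = id, length_nt = nchar(s), orf_start = orf$start,
                 orf_end = orf$end, orf_length_nt = orf$length_nt,
                 protein_length = nchar(prot),
                 mw_kda = round(molecularWeight(prot), 2),
                 pi = round(as.numeric(isoelectricPoint(prot)), 2))
    } else {
      data.frame(id = id, length_aa = nchar(s),
                 mw_kda = round(molecularWeight(s), 2),
                 pi = round(as.numeric(isoelectricPoint(s)), 2))
    }
  })
  do.call(rbind, rows)
}
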