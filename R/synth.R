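# Seeded synthetic-data generation: proteomes with planted RR-TZF
# architectures (plus broken-spacing decoys), qPCR Ct tables with planted
# fold changes, and germination counts with planted rates. Every generated
# object carries a ground truth the downstream stages can be scored against.

.SYNTH_CLASSES <- c("IIa", "IIa_extra_cys", "IIb", "groupI_ank",
                    "groupV_longspacer", "decoy_broken_spacing",
                    "decoy_random")

.FILLER_AA <- setdiff(names(.AA_AVG_MASS), c("C", "H"))

# Background residue frequencies: uniform over the 20 residues with C and H
# down-weighted x0.3 to keep spurious zinc-finger grammar hits rare.
.BG_AA <- names(.AA_AVG_MASS)
.BG_W <- ifelse(.BG_AA %in% c("C", "H"), 0.3, 1)
.BG_W <- .BG_W / sum(.BG_W)

.ANK_PROTOTYPE <- "DGNTPLHLAARNGHLEVVKLLLEAGADVNARDK"

.randBg <- function(n) sample(.BG_AA, n, replace = TRUE, prob = .BG_W)
.randFill <- function(n) sample(.FILLER_AA, n, replace = TRUE)

# Assemble the signature-conforming cassette. Literal segments (anchors and
# the invariant K/RR/Y/FE/HP/FFA residues) are immutable; filler runs are
# mutable. Break types knock exactly one spacer out of bounds.
.buildCassette <- function(s1 = 7L, breakType = NULL) {
  chchGap1 <- if (identical(breakType, "chch")) 7L else 5L
  s1Use <- if (identical(breakType, "ccch1")) 22L else s1
  cc2Gap1 <- if (identical(breakType, "ccch2")) 6L else 5L
  segs <- list(
    "K", 3L, c(mark = "chch"), chchGap1, "H", 4L, "C", 3L,
    c(markEnd = "chch"),
    6L, "RR", 6L, "Y", 4L, c(mark = "ccch1"), s1Use, "C", 5L, "C", 3L,
    c(markEnd = "ccch1"),
    2L, "FE", 3L, "HP", 7L, c(mark = "ccch2"), cc2Gap1, "C", 4L, "C",
    "FFA", c(markEnd = "ccch2"))
  chars <- character(0); mutable <- logical(0); marks <- list()
  for (sg in segs) {
    if (is.numeric(sg)) {
      chars <- c(chars, .randFill(sg))
      mutable <- c(mutable, rep(TRUE, sg))
    } else if (!is.null(names(sg))) {
      # marked anchor: the first C of a domain, or its terminal H
      pos <- length(chars) + 1L
      if (names(sg) == "mark") marks[[unname(sg)]] <- pos
      else marks[[paste0(unname(sg), "_end")]] <- pos
      chars <- c(chars, if (names(sg) == "mark") "C" else "H")
      mutable <- c(mutable, FALSE)
    } else {
      cc <- strsplit(sg, "")[[1]]
      chars <- c(chars, cc)
      mutable <- c(mutable, rep(FALSE, length(cc)))
    }
  }
  list(chars = chars, mutable = mutable, marks = marks)
}

.buildClassProtein <- function(class, s1 = 7L) {
  prefixLen <- sample(30:80, 1)
  suffixLen <- sample(50:150, 1)
  if (class == "decoy_random") {
    chars <- .randBg(sample(200:400, 1))
    return(list(chars = chars, mutable = rep(TRUE, length(chars)),
                marks = list()))
  }
  breakType <- if (class == "decoy_broken_spacing")
    sample(c("chch", "ccch1", "ccch2"), 1) else NULL
  if (class == "groupV_longspacer") s1 <- sample(10:20, 1)
  cas <- .buildCassette(s1 = s1, breakType = breakType)
  prefix <- .randBg(prefixLen)
  prefMut <- rep(TRUE, prefixLen)
  if (class == "groupI_ank") {
    ank <- strsplit(strrep(.ANK_PROTOTYPE, 3L), "")[[1]]
    prefix <- c(prefix, ank)
    prefMut <- c(prefMut, rep(FALSE, length(ank)))
    prefixLen <- length(prefix)
  }
  # pin the extra-Cys diagnostic position 12 residues upstream of the first
  # CHCH cysteine: planted C for the extra-Cys class, guaranteed non-C
  # otherwise, immutable for all classes so the truth label stays exact
  chchAbs <- prefixLen + cas$marks$chch
  ecPos <- chchAbs - 12L
  if (ecPos >= 1L) {
    prefix[ecPos] <- if (class == "IIa_extra_cys") "C" else "A"
    prefMut[ecPos] <- FALSE
  }
  chars <- c(prefix, cas$chars, .randBg(suffixLen))
  mutable <- c(prefMut, cas$mutable, rep(TRUE, suffixLen))
  marks <- lapply(cas$marks, function(p) p + prefixLen)
  list(chars = chars, mutable = mutable, marks = marks)
}

.mutateCopy <- function(proto, rate = 0.15) {
  chars <- proto$chars
  idx <- which(proto$mutable & stats::runif(length(chars)) < rate)
  if (length(idx)) chars[idx] <- .randFill(length(idx))
  out <- proto
  out$chars <- chars
  out
}

.classTruth <- function(class) {
  switch(class,
    IIa = , IIa_extra_cys = list(group = "II", subgroup = "IIa"),
    IIb = list(group = "II", subgroup = "IIb"),
    groupI_ank = list(group = "I", subgroup = "none"),
    groupV_longspacer = list(group = "V", subgroup = "none"),
    list(group = NA_character_, subgroup = NA_character_))
}

.verifyPlanted <- function(class, prot, grammars) {
  arch <- callArchitecture(AAStringSet(setNames(
    paste(prot$chars, collapse = ""), "q")), grammars = grammars)
  if (class %in% c("decoy_broken_spacing", "decoy_random"))
    return(!arch$is_rr_tzf)
  isTRUE(arch$is_rr_tzf) &&
    identical(arch$chch_start, prot$marks$chch) &&
    identical(arch$ccch1_start, prot$marks$ccch1) &&
    identical(arch$ccch2_start, prot$marks$ccch2) &&
    (class != "IIa_extra_cys" || isTRUE(arch$extra_cys)) &&
    (class == "IIa_extra_cys" || !isTRUE(arch$extra_cys))
}

# Class prototypes drawn from a fixed prototype seed shared with
# syntheticReferenceSet(), so planted family members are recognizable
# homologs of the bundled exemplars.
.classPrototypes <- function(prototypeSeed = 7301L, grammars = builtinGrammars()) {
  .withSeed(prototypeSeed, {
    protos <- list()
    for (cl in c("IIa", "IIb", "groupI_ank", "groupV_longspacer",
                 "III", "IV")) {
      buildCl <- switch(cl, III = "IIa", IV = "IIb", cl)
      s1 <- switch(cl, IIb = 8L, IV = 8L, 7L)
      for (try in 1:20) {
        p <- .buildClassProtein(buildCl, s1 = s1)
        if (.verifyPlanted(buildCl, p, grammars)) break
        if (try == 20) stop("could not build a verified prototype for ", cl)
      }
      protos[[cl]] <- p
    }
    # the extra-Cys carriers are IIa members: same prototype, diagnostic
    # cysteine planted 12 residues upstream of the first CHCH cysteine
    ec <- protos$IIa
    ec$chars[ec$marks$chch - 12L] <- "C"
    if (!.verifyPlanted("IIa_extra_cys", ec, grammars))
      stop("could not derive a verified extra-Cys prototype")
    protos$IIa_extra_cys <- ec
    protos
  })
}

#' Bundled synthetic reference exemplars
#'
#' A labelled, user-replaceable exemplar set built from the same fixed
#' family prototypes as [generateProteome()]: one group-I (ankyrin-bearing)
#' exemplar, two each for subgroups IIa and IIb, and one each for groups
#' III, IV and V. All sequences are synthetic constructs (no database
#' sequences are bundled); real exemplars can be supplied as any
#' `AAStringSet` with `mcols` columns `group` and `subgroup`.
#'
#' @param prototypeSeed seed fixing the family prototypes (default 7301,
#'   the package-wide prototype seed).
#' @return `AAStringSet` with `mcols(x)$group` in I..V and
#'   `mcols(x)$subgroup` in IIa/IIb/none.
#' @export
syntheticReferenceSet <- function(prototypeSeed = 7301L) {
  protos <- .classPrototypes(prototypeSeed)
  variant <- function(p, seed) .withSeed(seed, .mutateCopy(p, rate = 0.08))
  seqs <- c(
    REF_I_1 = paste(protos$groupI_ank$chars, collapse = ""),
    REF_IIa_1 = paste(protos$IIa$chars, collapse = ""),
    REF_IIa_2 = paste(variant(protos$IIa, prototypeSeed + 1L)$chars,
                      collapse = ""),
    REF_IIb_1 = paste(protos$IIb$chars, collapse = ""),
    REF_IIb_2 = paste(variant(protos$IIb, prototypeSeed + 2L)$chars,
                      collapse = ""),
    REF_III_1 = paste(protos$III$chars, collapse = ""),
    REF_IV_1 = paste(protos$IV$chars, collapse = ""),
    REF_V_1 = paste(protos$groupV_longspacer$chars, collapse = ""))
  out <- AAStringSet(seqs)
  mcols(out)$group <- c("I", "II", "II", "II", "II", "III", "IV", "V")
  mcols(out)$subgroup <- c("none", "IIa", "IIa", "IIb", "IIb", "none",
                           "none", "none")
  mcols(out)$provenance <- "synthetic exemplar (rrtzf prototype seed)"
  out
}

#' Generate a synthetic proteome with planted RR-TZF architectures
#'
#' Each non-decoy protein is a mutated copy of its class prototype: a
#' random-background protein with an exact signature-conforming cassette
#' (CHCH motif, first CCCH domain with the class spacer, 16-residue linker,
#' canonical second CCCH domain) planted in it. `IIa_extra_cys` adds the
#' diagnostic cysteine 12 residues upstream of the CHCH; `groupI_ank` adds
#' three exact ankyrin-consensus repeats; `groupV_longspacer` draws the
#' first spacer from 10-20. `decoy_broken_spacing` proteins carry a cassette
#' with exactly one spacer knocked out of bounds; `decoy_random` proteins
#' are pure background. Planted classes and broken decoys are self-verified
#' against the architecture caller (bounded retries), so the recorded truth
#' coordinates are exact by construction.
#'
#' @param counts named integer vector over the classes
#'   `r paste(.SYNTH_CLASSES, collapse = ", ")` (missing classes = 0).
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @param prototypeSeed seed fixing the class prototypes (default 7301).
#' @param mutationRate per-position mutation rate for planted copies.
#' @return list with `proteins` (`AAStringSet`) and `truth` (data.frame:
#'   `id`, `class`, `expected_group`, `expected_subgroup`, `chch_start`,
#'   `ccch1_start`, `ccch2_start`, `signature_expected`).
#' @export
generateProteome <- function(counts, seed, prototypeSeed = 7301L,
                             mutationRate = 0.15) {
  if (missing(seed)) stop("a seed is mandatory")
  bad <- setdiff(names(counts), .SYNTH_CLASSES)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  full <- setNames(integer(length(.SYNTH_CLASSES)), .SYNTH_CLASSES)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("counts must be >= 0")
  grammars <- builtinGrammars()
  protos <- .classPrototypes(prototypeSeed, grammars)
  .withSeed(seed, {
    seqs <- character(0); truthRows <- list()
    for (cl in .SYNTH_CLASSES) {
      n <- full[[cl]]
      if (n == 0L) next
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in 1:20) {
          p <- if (cl %in% c("decoy_broken_spacing", "decoy_random"))
            .buildClassProtein(cl)
          else .mutateCopy(protos[[cl]], rate = mutationRate)
          verified <- if (cl == "decoy_random") TRUE
            else .verifyPlanted(cl, p, grammars)
          if (verified) { ok <- TRUE; break }
        }
        if (!ok) stop("failed to build a verified '", cl, "' protein")
        id <- paste0(cl, "_", i)
        seqs[id] <- paste(p$chars, collapse = "")
        tr <- .classTruth(cl)
        truthRows[[id]] <- data.frame(
          id = id, class = cl, expected_group = tr$group,
          expected_subgroup = tr$subgroup,
          chch_start = if (is.null(p$marks$chch)) NA_integer_ else
            p$marks$chch,
          ccch1_start = if (is.null(p$marks$ccch1)) NA_integer_ else
            p$marks$ccch1,
          ccch2_start = if (is.null(p$marks$ccch2)) NA_integer_ else
            p$marks$ccch2,
          signature_expected = cl %in% c("IIa", "IIa_extra_cys", "IIb",
                                         "groupI_ank"),
          stringsAsFactors = FALSE)
      }
    }
    proteins <- AAStringSet(seqs)
    truth <- do.call(rbind, truthRows)
    if (is.null(truth))
      truth <- data.frame(id = character(0), class = character(0))
    rownames(truth) <- NULL
    list(proteins = proteins, truth = truth)
  })
}

#' Generate a synthetic long-format qPCR Ct table
#'
#' Target Ct values are `ctBase - planted_log2_fc` plus Gaussian noise per
#' technical observation; the reference gene sits at `refBase` plus the same
#' noise model. The calibrator group must be present with a planted fold
#' change of 0.
#'
#' @param plantedLog2Fc named numeric vector: planted log2 fold change per
#'   sample group (e.g. treatment-by-time labels).
#' @param calibratorGroup name of the baseline group (planted value 0).
#' @param targetGene,referenceGene gene names to emit.
#' @param ctBase,refBase baseline Ct of target and reference gene.
#' @param noiseSd Gaussian Ct noise sd (default 0.15 cycles).
#' @param nBio,nTech biological / technical replicates.
#' @param seed RNG seed.
#' @return list with `table` (readCtTable-shaped data.frame) and `truth`
#'   (data.frame group / planted_log2_fc).
#' @export
generateCtTable <- function(plantedLog2Fc, calibratorGroup,
                            targetGene = "target", referenceGene = "ref",
                            ctBase = 24, refBase = 18, noiseSd = 0.15,
                            nBio = 3L, nTech = 3L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (!calibratorGroup %in% names(plantedLog2Fc) ||
      plantedLog2Fc[[calibratorGroup]] != 0)
    stop("calibrator group must be present with planted log2 fc = 0")
  .withSeed(seed, {
    rows <- list()
    for (g in names(plantedLog2Fc)) for (b in seq_len(nBio)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = c(rep(targetGene, nTech), rep(referenceGene, nTech)),
        group = g, bio_rep = b, tech_rep = rep(seq_len(nTech), 2L),
        ct = c(ctBase - plantedLog2Fc[[g]] + stats::rnorm(nTech, 0, noiseSd),
               refBase + stats::rnorm(nTech, 0, noiseSd)),
        stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows),
         truth = data.frame(group = names(plantedLog2Fc),
                            planted_log2_fc = unname(plantedLog2Fc),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic germination count table
#'
#' Binomial draws at the planted germination rates, emulating replicated
#' 50-100 seed germination assays per genotype and condition.
#'
#' @param design data.frame with columns `genotype`, `condition`, `rate`.
#' @param totalSeeds seeds per replicate (default 80).
#' @param nRep replicates per design cell (default 3).
#' @param seed RNG seed.
#' @return list with `table` (readGerminationTable-shaped data.frame) and
#'   `truth` (the design).
#' @export
generateGermination <- function(design, totalSeeds = 80L, nRep = 3L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(all(c("genotype", "condition", "rate") %in% names(design)),
            all(design$rate >= 0 & design$rate <= 1))
  .withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(design)), function(i)
      data.frame(genotype = design$genotype[i],
                 condition = design$condition[i], rep = seq_len(nRep),
                 germinated = stats::rbinom(nRep, totalSeeds,
                                            design$rate[i]),
                 total = totalSeeds, stringsAsFactors = FALSE)))
    list(table = rows, truth = design)
  })
}
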