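# End-to-end pipeline: architecture -> classification -> consensus -> tree,
# with a fail-fast config object echoed into every output's metadata header.

#' Pipeline run configuration
#'
#' Collects every tunable threshold with its default; unrecognized names
#' are an error (fail-fast). Defaults: 23 percent minimum similarity for
#' the homology step, linker bounds (10, 25) around the signature-fixed
#' 16-residue linker, extra-Cys offset 12, 1000 bootstrap replicates with a
#' 50 percent display filter.
#'
#' @param ... overrides for `minSimilarity`, `linkerRange`,
#'   `extraCysOffset`, `bootstrap`, `supportFilter`, `seed`.
#' @return named list of validated settings.
#' @export
tzfConfig <- function(...) {
  cfg <- list(minSimilarity = 23, linkerRange = c(10L, 25L),
              extraCysOffset = 12L, bootstrap = 1000L, supportFilter = 50,
              seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unrecognized config key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$minSimilarity >= 0, cfg$minSimilarity <= 100,
            length(cfg$linkerRange) == 2L,
            cfg$linkerRange[1] <= cfg$linkerRange[2],
            cfg$extraCysOffset >= 1, cfg$bootstrap >= 0,
            cfg$supportFilter >= 0, cfg$supportFilter <= 100)
  cfg
}

.cfgMeta <- function(cfg) {
  vapply(names(cfg), function(k)
    paste(format(cfg[[k]], trim = TRUE), collapse = ","), character(1))
}

#' Run the full RR-TZF pipeline on a protein set
#'
#' Stages: architecture calling (accepted vs excluded reports), group and
#' subgroup classification against the reference exemplars, consensus
#' signature of the accepted proteins (over a constructed multiple
#' alignment), and a neighbor-joining tree with bootstrap supports when at
#' least four family members are found. All outputs are TSV/Newick/plain
#' text under `outDir`, each carrying the configuration in `#` header
#' lines; reruns with identical inputs and config are byte-identical.
#'
#' @param proteins `AAStringSet` (e.g. from [readFasta()] or
#'   [generateProteome()]).
#' @param outDir output directory (created if missing).
#' @param refs labelled exemplar set (default [syntheticReferenceSet()]).
#' @param config see [tzfConfig()].
#' @param ankTable optional domain-annotation table for [detectAnk()].
#' @return invisibly, a list with the in-memory results (`architecture`,
#'   `classification`, `signature`, `tree`).
#' @export
runPipeline <- function(proteins, outDir, refs = syntheticReferenceSet(),
                        config = tzfConfig(), ankTable = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- .cfgMeta(config)
  arch <- callArchitecture(proteins, linkerRange = config$linkerRange,
                           extraCysOffset = config$extraCysOffset,
                           ankTable = ankTable)
  rep <- excludedReport(arch)
  writeTsvReport(arch, file.path(outDir, "architecture.tsv"), meta)
  writeTsvReport(rep$excluded, file.path(outDir, "excluded.tsv"), meta)
  acc <- proteins[arch$is_rr_tzf]
  cls <- NULL; sig <- NULL; tree <- NULL
  if (length(acc) > 0L) {
    sub <- assignSubgroup(acc, arch, refs,
                          minSimilarity = config$minSimilarity)
    grp <- assignGroup(acc, arch, refs)
    cls <- merge(grp, sub[c("protein_id", "subgroup", "best_similarity")],
                 by = "protein_id", suffixes = c("", "_subgroup"))
    cls <- cls[order(match(cls$protein_id, names(acc))), ]
    writeTsvReport(cls, file.path(outDir, "classification.tsv"), meta)
  }
  if (length(acc) >= 2L) {
    msa <- progressiveMsa(acc)
    sig <- consensusSignature(msa)
    writeLines(sig, file.path(outDir, "consensus_signature.txt"))
    if (length(acc) >= 4L) {
      tree <- bootstrapSupport(msa, replicates = config$bootstrap,
                               seed = config$seed)
      tree <- filterSupports(tree, min = config$supportFilter)
      writeNewick(tree, file.path(outDir, "tree.nwk"))
    }
  }
  invisible(list(architecture = arch, classification = cls,
                 signature = sig, tree = tree))
}
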