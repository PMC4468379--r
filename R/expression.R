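#' @importFrom stats aggregate aov pt sd
#' @importFrom mvtnorm pmvt
NULL

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged first; per (group, biological
#' replicate) the target Ct is normalized to the reference gene
#' (`dct = Ct_target - Ct_reference`), then to the mean dCt of the
#' calibrator group (`ddct`), and exponentiated (`ratio = 2^-ddct`,
#' `log2_ratio = -ddct`). Summary rows give the mean log2 ratio and its
#' standard error across biological replicates.
#'
#' @param table long-format Ct table (see [readCtTable()]).
#' @param targetGene,referenceGene gene names in the table.
#' @param calibratorGroup group whose mean dCt defines the baseline.
#' @return list with `per_rep` (gene, group, bio_rep, dct, ddct, ratio,
#'   log2_ratio) and `summary` (gene, group, n, mean_log2, se_log2,
#'   mean_ratio).
#' @export
ddct <- function(table, targetGene, referenceGene, calibratorGroup) {
  need <- c("gene", "group", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table is missing column(s): ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (!targetGene %in% table$gene) stop("target gene not in table")
  tech <- aggregate(ct ~ gene + group + bio_rep, data = table, FUN = mean)
  tgt <- tech[tech$gene == targetGene, ]
  ref <- tech[tech$gene == referenceGene, ]
  key <- function(d) paste(d$group, d$bio_rep, sep = "\r")
  missingRef <- setdiff(key(tgt), key(ref))
  if (length(missingRef))
    stop("reference gene '", referenceGene, "' missing for (group, bio_rep): ",
         paste(gsub("\r", "/", missingRef), collapse = ", "))
  tgt$dct <- tgt$ct - ref$ct[match(key(tgt), key(ref))]
  cal <- tgt$dct[tgt$group == calibratorGroup]
  if (length(cal) == 0L)
    stop("calibrator group '", calibratorGroup, "' absent for target gene")
  tgt$ddct <- tgt$dct - mean(cal)
  tgt$ratio <- 2^(-tgt$ddct)
  tgt$log2_ratio <- -tgt$ddct
  perRep <- tgt[order(tgt$group, tgt$bio_rep),
                c("gene", "group", "bio_rep", "dct", "ddct", "ratio",
                  "log2_ratio")]
  rownames(perRep) <- NULL
  sm <- do.call(rbind, lapply(split(perRep, perRep$group), function(g)
    data.frame(gene = targetGene, group = g$group[1], n = nrow(g),
               mean_log2 = mean(g$log2_ratio),
               se_log2 = if (nrow(g) > 1L)
                 sd(g$log2_ratio) / sqrt(nrow(g)) else NA_real_,
               mean_ratio = mean(g$ratio), stringsAsFactors = FALSE)))
  rownames(sm) <- NULL
  list(per_rep = perRep, summary = sm)
}

#' One-way ANOVA with Bonferroni or Dunnett post hoc tests
#'
#' Bonferroni: all pairwise t statistics on the pooled ANOVA mean square,
#' with raw two-sided p-values multiplied by the number of contrasts and
#' capped at 1. Dunnett: many-to-one comparisons against `controlGroup`,
#' two-sided p-values from the equicorrelated multivariate-t distribution
#' (correlation `sqrt(lambda_i * lambda_j)` with
#' `lambda_i = n_i / (n_i + n_0)`). Significance is flagged at 0.05 and
#' 0.01.
#'
#' @param values numeric response (e.g. log2 ratios or angular-transformed
#'   germination ratios).
#' @param groups factor/character of group labels (same length).
#' @param method `"bonferroni"` or `"dunnett"`.
#' @param controlGroup control label (required for Dunnett).
#' @return data.frame: `contrast`, `estimate`, `t`, `df`, `p`, `sig_05`,
#'   `sig_01`; attribute `anova_p` holds the omnibus F-test p-value.
#' @export
anovaPosthoc <- function(values, groups, method = c("bonferroni", "dunnett"),
                         controlGroup = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("every group needs >= 2 values (group(s) ",
         paste(names(tab)[tab < 2L], collapse = ", "), " have fewer)")
  fit <- aov(values ~ factor(groups))
  ms <- summary(fit)[[1]]
  mse <- ms["Residuals", "Mean Sq"]
  df <- ms["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  ns <- as.numeric(tab[names(means)])
  names(ns) <- names(means)
  if (method == "bonferroni") {
    gs <- names(means)
    pairs <- utils::combn(gs, 2, simplify = FALSE)
    k <- length(pairs)
    out <- do.call(rbind, lapply(pairs, function(pr) {
      est <- means[pr[1]] - means[pr[2]]
      se <- sqrt(mse * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
      tt <- est / se
      praw <- 2 * pt(-abs(tt), df)
      data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = unname(est),
                 t = unname(tt), df = df, p = min(1, k * praw),
                 stringsAsFactors = FALSE)
    }))
  } else {
    if (is.null(controlGroup) || !controlGroup %in% names(means))
      stop("Dunnett requires a 'controlGroup' present in the data")
    others <- setdiff(names(means), controlGroup)
    n0 <- ns[controlGroup]
    lambda <- ns[others] / (ns[others] + n0)
    R <- sqrt(outer(lambda, lambda))
    diag(R) <- 1
    tt <- vapply(others, function(g)
      unname((means[g] - means[controlGroup]) /
               sqrt(mse * (1 / ns[g] + 1 / n0))), numeric(1))
    out <- do.call(rbind, lapply(seq_along(others), function(i) {
      p <- 1 - pmvt(lower = rep(-abs(tt[i]), length(others)),
                    upper = rep(abs(tt[i]), length(others)),
                    df = as.integer(df), corr = R, sigma = NULL)[1]
      data.frame(contrast = paste(others[i], "-", controlGroup),
                 estimate = unname(means[others[i]] - means[controlGroup]),
                 t = tt[i], df = df, p = min(1, max(0, p)),
                 stringsAsFactors = FALSE)
    }))
  }
  out$sig_05 <- out$p < 0.05
  out$sig_01 <- out$p < 0.01
  rownames(out) <- NULL
  attr(out, "anova_p") <- ms[1, "Pr(>F)"]
  out
}

#' Angular (arcsine-square-root) transform of a proportion
#'
#' Variance-stabilizing transform applied to germination ratios before
#' ANOVA: `asin(sqrt(p))`.
#'
#' @param p proportion(s) in \[0, 1\].
#' @return transformed value(s) in \[0, pi/2\].
#' @export
angularTransform <- function(p) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' log2 transform of expression ratios
#' @param ratios positive ratios.
#' @return log2 values (ratio 1 -> 0).
#' @export
log2Transform <- function(ratios) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  log2(ratios)
}

#' Germination-rate ANOVA with post hoc tests
#'
#' Applies the angular transform to per-replicate germination ratios and
#' runs [anovaPosthoc()] across genotypes within each condition.
#'
#' @param table germination table (see [readGerminationTable()]).
#' @param method,controlGroup passed to [anovaPosthoc()] (control is a
#'   genotype label).
#' @return named list of per-condition post hoc tables.
#' @export
germinationTest <- function(table, method = c("dunnett", "bonferroni"),
                            controlGroup = NULL) {
  method <- match.arg(method)
  lapply(split(table, table$condition), function(d) {
    anovaPosthoc(angularTransform(d$germinated / d$total), d$genotype,
                 method = method, controlGroup = controlGroup)
  })
}
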