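flatCt <- function(groups, targetCt, refCt = 18, nBio = 3, nTech = 3) {
  do.call(rbind, lapply(seq_along(groups), function(i)
    do.call(rbind, lapply(seq_len(nBio), function(b)
      data.frame(gene = rep(c("tgt", "ref"), each = nTech),
                 group = groups[i], bio_rep = b,
                 tech_rep = rep(seq_len(nTech), 2),
                 ct = c(rep(targetCt[i], nTech), rep(refCt, nTech)))))))
}

test_that("ddCt reduces to closed forms in noise-free tables", {
  # target equals reference everywhere -> all ratios 1
  tab <- flatCt(c("cal", "trt"), c(18, 18))
  res <- ddct(tab, "tgt", "ref", "cal")
  expect_true(all(res$per_rep$ratio == 1))
  expect_true(all(res$per_rep$log2_ratio == -res$per_rep$ddct))

  # one cycle earlier than the calibrator -> ratio 2
  tab <- flatCt(c("cal", "trt"), c(24, 23))
  res <- ddct(tab, "tgt", "ref", "cal")
  expect_identical(res$summary$mean_ratio[res$summary$group == "trt"], 2)
  expect_identical(res$summary$mean_ratio[res$summary$group == "cal"], 1)

  # technical replicates are averaged before any delta is formed
  tab <- flatCt(c("cal", "trt"), c(24, 23))
  tab$ct[tab$gene == "tgt" & tab$group == "trt"] <- c(22, 23, 24, 23, 23, 23,
                                                      22.5, 23, 23.5)
  res <- ddct(tab, "tgt", "ref", "cal")
  expect_equal(res$summary$mean_ratio[res$summary$group == "trt"], 2)
})

test_that("ddCt is invariant to per-sample Ct shifts and errors are named", {
  sim <- generateCtTable(c(cal = 0, t1 = 1.5), "cal", seed = 41)
  res1 <- ddct(sim$table, "target", "ref", "cal")
  shifted <- sim$table
  # shift every Ct within one (group, bio_rep) block by a constant
  sel <- shifted$group == "t1" & shifted$bio_rep == 2
  shifted$ct[sel] <- shifted$ct[sel] + 3.7
  res2 <- ddct(shifted, "target", "ref", "cal")
  expect_equal(res1$per_rep$ratio, res2$per_rep$ratio, tolerance = 1e-12)

  broken <- sim$table[!(sim$table$gene == "ref" & sim$table$group == "t1" &
                          sim$table$bio_rep == 1), ]
  expect_error(ddct(broken, "target", "ref", "cal"), "t1/1")
  expect_error(ddct(sim$table, "target", "ref", "nope"), "calibrator")
  expect_error(ddct(sim$table, "nope", "ref", "cal"), "target")
})

test_that("planted fold changes across the grid are recovered with low bias", {
  fc <- c(cal = 0, m2 = -2, m1 = -1, z = 0, p1 = 1, p2 = 2)
  errs <- sapply(1:120, function(s) {
    sim <- generateCtTable(fc, "cal", noiseSd = 0.15, nBio = 3, seed = 5000 + s)
    res <- ddct(sim$table, "target", "ref", "cal")
    sm <- res$summary[res$summary$group != "cal", ]
    sm$mean_log2 - fc[sm$group]
  })
  expect_lt(max(abs(rowMeans(errs))), 0.1)
})

test_that("Bonferroni equals k times the pooled t-test, capped at one", {
  set.seed(42)
  v <- c(rnorm(3, 0), rnorm(3, 5), rnorm(3, 5.1))
  g <- rep(c("a", "b", "c"), each = 3)
  out <- anovaPosthoc(v, g, "bonferroni")
  expect_identical(nrow(out), 3L)
  fit <- aov(v ~ factor(g))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  df <- summary(fit)[[1]]["Residuals", "Df"]
  means <- tapply(v, g, mean)
  tRaw <- (means["a"] - means["b"]) / sqrt(mse * (2 / 3))
  expect_equal(out$p[out$contrast == "a - b"],
               min(1, 3 * 2 * pt(-abs(tRaw), df)))
  # identical groups -> capped p of 1
  same <- anovaPosthoc(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3),
                       "bonferroni")
  expect_true(all(same$p == 1))
})

test_that("clearly separated groups are significant at the 0.01 level", {
  v <- c(0.0, 0.1, -0.1, 10.0, 10.1, 9.9)
  g <- rep(c("ctl", "trt"), each = 3)
  expect_true(anovaPosthoc(v, g, "bonferroni")$sig_01)
  expect_true(anovaPosthoc(v, g, "dunnett", controlGroup = "ctl")$sig_01)
})

test_that("Dunnett p-values agree with the multcomp reference", {
  skip_if_not_installed("multcomp")
  set.seed(43)
  v <- c(rnorm(4, 0), rnorm(4, 1.2), rnorm(4, 0.3), rnorm(4, -0.8))
  g <- factor(rep(c("ctl", "a", "b", "c"), each = 4),
              levels = c("ctl", "a", "b", "c"))
  mine <- anovaPosthoc(v, as.character(g), "dunnett", controlGroup = "ctl")
  fit <- stats::aov(v ~ g)
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  refP <- as.numeric(ref$test$pvalues)
  names(refP) <- sub(" - ctl.*", "", names(ref$test$coefficients))
  mineP <- setNames(mine$p, sub(" - ctl", "", mine$contrast))
  expect_equal(mineP[names(refP)], refP, tolerance = 5e-3)
})

test_that("Dunnett holds its familywise type-I error on null data", {
  set.seed(44)
  rej <- vapply(1:400, function(s) {
    v <- rnorm(12)
    g <- rep(c("ctl", "a", "b", "d"), each = 3)
    any(anovaPosthoc(v, g, "dunnett", controlGroup = "ctl")$p < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("degenerate designs are refused with clear errors", {
  expect_error(anovaPosthoc(c(1, 2), c("a", "b")), ">= 2 values")
  expect_error(anovaPosthoc(c(1, 2, 3), c("a", "a", "a")), "2 groups")
  expect_error(anovaPosthoc(c(1, 2, 3, 4), rep(c("a", "b"), 2), "dunnett"),
               "controlGroup")
})

test_that("the angular and log2 transforms hit their closed-form anchors", {
  expect_identical(angularTransform(0), 0)
  expect_equal(angularTransform(1), pi / 2)
  expect_equal(angularTransform(0.5), pi / 4)
  expect_error(angularTransform(1.2), "\\[0, 1\\]")
  expect_identical(log2Transform(1), 0)
  expect_equal(log2Transform(c(2, 0.5)), c(1, -1))
  expect_error(log2Transform(0), "positive")
})

test_that("germination analysis flags planted genotype effects per condition", {
  design <- data.frame(genotype = rep(c("wt", "att", "oe"), 2),
                       condition = rep(c("water", "NaCl"), each = 3),
                       rate = c(0.95, 0.95, 0.95, 0.5, 0.85, 0.12))
  sim <- generateGermination(design, totalSeeds = 80, nRep = 3, seed = 45)
  res <- germinationTest(sim$table, method = "dunnett", controlGroup = "wt")
  expect_named(res, c("NaCl", "water"))
  nacl <- res$NaCl
  expect_true(all(nacl$sig_01))
  expect_false(any(res$water$sig_05))
})
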