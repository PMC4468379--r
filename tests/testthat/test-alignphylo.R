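test_that("global alignment scores match exhaustive enumeration on tiny inputs", {
  al <- globalAlign("MKVC", "MKVC")
  expect_identical(al$identity, 100)
  expect_identical(al$aligned_a, "MKVC")

  # linear-gap setting comparable with the recursive oracle
  S <- get(".BLOSUM62", envir = asNamespace("rrtzf"))
  pairs <- list(c("ACD", "AD"), c("MKV", "MV"), c("WW", "WAW"),
                c("ACDE", "CE"), c("KK", "KK"))
  for (pr in pairs) {
    got <- globalAlign(pr[1], pr[2], gapOpening = 0, gapExtend = 2)$score
    want <- oracleAlignScore(pr[1], pr[2], S, gapPer = 2)
    expect_equal(got, want)
  }
  al <- globalAlign("ACD", "AD")
  expect_identical(nchar(al$aligned_a), nchar(al$aligned_b))
  expect_identical(sum(strsplit(al$aligned_b, "")[[1]] == "-"), 1L)

  al <- globalAlign("", "MKV")
  expect_identical(al$identity, 0)
  expect_identical(al$aligned_a, "---")
})

test_that("neighbor joining recovers a known additive quartet exactly", {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5; d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6; d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- njTree(d)
  expect_identical(max(abs(cophenetic(tr)[rownames(d), rownames(d)] - d)), 0)
  # AB|CD is the generating split
  parts <- ape::prop.part(ape::unroot(tr))
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  hasSplit <- function(s) any(vapply(splits, identical, logical(1), s))
  expect_true(hasSplit(c("A", "B")) || hasSplit(c("C", "D")))
})

test_that("3 taxa resolve by the closed-form three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)
})

test_that("NJ reproduces random additive matrices to numerical precision", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    gen <- randomAdditiveMatrix(n)
    tr <- njTree(gen$d)
    expect_lt(max(abs(cophenetic(tr)[rownames(gen$d), rownames(gen$d)] -
                        gen$d)), 1e-9)
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr),
                                               ape::unroot(gen$tree))), 0)
  }
})

test_that("NJ bipartitions are invariant under taxon permutation", {
  set.seed(203)
  gen <- randomAdditiveMatrix(6)
  tr1 <- njTree(gen$d)
  perm <- sample(rownames(gen$d))
  tr2 <- njTree(gen$d[perm, perm])
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr1),
                                             ape::unroot(tr2))), 0)
})

test_that("equidistant taxa resolve deterministically by the tie rule", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- njTree(d); t2 <- njTree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap supports are seeded, reproducible and high for clear clades", {
  sim <- generateProteome(c(IIa = 2, IIb = 2, groupI_ank = 2,
                            groupV_longspacer = 2), seed = 5)
  msa <- progressiveMsa(sim$proteins)
  tr <- bootstrapSupport(msa, replicates = 100, seed = 3)
  pairs <- split(names(sim$proteins),
                 sub("_[0-9]+$", "", names(sim$proteins)))
  supp <- trueCladeSupports(tr, pairs)
  expect_false(anyNA(supp))
  expect_true(all(supp >= 95))
  tr2 <- bootstrapSupport(msa, replicates = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # replicates = 0 yields a bare tree
  expect_null(bootstrapSupport(msa, replicates = 0)$node.label)
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  sim <- generateProteome(c(IIa = 2, IIb = 2, groupI_ank = 2), seed = 6)
  msa <- progressiveMsa(sim$proteins)
  tr <- bootstrapSupport(msa, replicates = 50, seed = 2)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  back <- ape::read.tree(f)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(back),
                                             ape::unroot(tr))), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-8)
  expect_setequal(back$node.label, tr$node.label)
})

test_that("support filtering blanks values below the display threshold", {
  tr <- ape::read.tree(text = "((a:1,b:1)40:1,(c:1,d:1)92:1);")
  out <- filterSupports(tr, min = 50)
  expect_identical(sort(out$node.label), sort(c(tr$node.label[1], "", "92")))
})

test_that("the progressive aligner reproduces residues and aligns homologs", {
  sim <- generateProteome(c(IIa = 4), seed = 8)
  msa <- progressiveMsa(sim$proteins)
  expect_identical(length(unique(Biostrings::width(msa))), 1L)
  expect_identical(as.character(degap(msa)), as.character(sim$proteins))
  # close homologs align with near-perfect column identity at the anchors
  arch <- callArchitecture(sim$proteins)
  prof <- conservationProfile(msa)
  expect_gt(mean(prof$identity == 1), 0.5)
})
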