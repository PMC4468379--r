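QUERY_PEPTIDE <- "IDAYSCDHFRMYDFKVRRCARGRSHDWTECPYAH"

# Exact signature-conforming cassette with 'A' fillers and a configurable
# first-domain spacer; prefixed so coordinates are away from the terminus.
cassette <- function(s1 = 7L, gap1 = 5L, prefix = strrep("G", 20L),
                     rr = "RR") {
  paste0(prefix,
         "K", "AAA", "C", strrep("A", gap1), "H", "AAAA", "C", "AAA", "H",
         strrep("A", 6), rr, strrep("A", 6), "Y", strrep("A", 4),
         "C", strrep("A", s1), "C", strrep("A", 5), "C", strrep("A", 3), "H",
         "AA", "FE", "AAA", "HP", strrep("A", 7),
         "C", strrep("A", 5), "C", strrep("A", 4), "C", "FFA", "H")
}

test_that("a signature-conforming protein is called RR-TZF with canonical spacing", {
  arch <- callArchitecture(cassette(7))
  expect_true(arch$is_rr_tzf)
  expect_identical(arch$spacer1_length, 7L)
  expect_identical(arch$spacer_class, "canonical_7_8")
  expect_identical(arch$ccch2_variant, "canonical")
  expect_identical(arch$linker_length, 16L)
  expect_true(arch$tandem_ok)
  expect_false(is.na(arch$signature_start))
  expect_identical(arch$chch_start, 25L)  # first CHCH cysteine
})

test_that("the query peptide extended with a tandem CCCH pair passes the filter", {
  prot <- paste0(QUERY_PEPTIDE, strrep("A", 10),
                 "C", strrep("A", 7), "C", strrep("A", 5), "C",
                 strrep("A", 3), "H", strrep("A", 16),
                 "C", strrep("A", 5), "C", strrep("A", 4), "C",
                 strrep("A", 3), "H")
  arch <- callArchitecture(prot)
  expect_true(arch$is_rr_tzf)
  expect_identical(arch$chch_start, 19L)
  expect_identical(arch$spacer_class, "canonical_7_8")
  expect_true(arch$tandem_ok)
})

test_that("stretched and broken spacings reclassify or fail the filter", {
  a20 <- callArchitecture(cassette(20))
  expect_true(a20$is_rr_tzf)
  expect_identical(a20$spacer_class, "long_10_20")
  expect_true(is.na(a20$signature_start))  # signature demands 7-8

  a9 <- callArchitecture(cassette(9))
  expect_true(a9$is_rr_tzf)
  expect_identical(a9$spacer_class, "nine")
  expect_true(is.na(a9$signature_start))

  # CHCH knocked out: the arginine-rich region alone no longer qualifies
  noChch <- callArchitecture(cassette(7, gap1 = 7))
  expect_false(noChch$is_rr_tzf)
  expect_true(is.na(noChch$chch_start))

  rep <- excludedReport(callArchitecture(
    Biostrings::AAStringSet(c(ok = cassette(7), broken = cassette(7, gap1 = 7),
                              blank = strrep("P", 60)))))
  expect_identical(rep$accepted$protein_id, "ok")
  expect_identical(rep$excluded$protein_id, "broken")
  expect_identical(rep$blank$protein_id, "blank")
})

test_that("the extra cysteine is detected at the configured upstream offset", {
  base <- cassette(7)
  arch <- callArchitecture(base)
  expect_false(arch$extra_cys)
  pos <- arch$chch_start - 12L
  planted <- paste0(substr(base, 1, pos - 1L), "C",
                    substr(base, pos + 1L, nchar(base)))
  expect_true(callArchitecture(planted)$extra_cys)
  expect_true(checkExtraCys(planted, arch$chch_start))
  # offset is a knob: at -13 the planted residue is no longer the hit
  expect_false(checkExtraCys(planted, arch$chch_start, offset = 13L))
  expect_warning(res <- checkExtraCys(cassette(7, prefix = strrep("G", 5)),
                                      10L), "out of range")
  expect_false(res)
})

test_that("ankyrin repeats are counted from tables or the built-in consensus", {
  tab <- data.frame(protein_id = c("p1", "p1", "p2"),
                    domain = c("ANK", "ANK", "PF00023"),
                    start = c(1, 40, 1), end = c(33, 72, 33))
  expect_identical(detectAnk("MKV", "p1", "annotation_table", tab), 2L)
  expect_identical(detectAnk("MKV", "p2", "annotation_table", tab), 0L)
  expect_error(detectAnk("MKV", "p1", "annotation_table"), "ankTable")

  ankProto <- "DGNTPLHLAARNGHLEVVKLLLEAGADVNARDK"
  expect_identical(detectAnk(strrep(ankProto, 3), source = "builtin_consensus"),
                   3L)
  expect_identical(detectAnk(strrep("A", 120), source = "builtin_consensus"),
                   0L)
})

test_that("signature scanning is leftmost, ends in CFFAH, and implies the filter", {
  s <- cassette(7)
  sig <- signatureScan(s)
  expect_false(is.null(sig))
  expect_identical(substr(s, sig$end - 4L, sig$end), "CFFAH")
  expect_null(signatureScan(cassette(7, rr = "RA")))

  # signature hit => is_rr_tzf on a mixed random/planted set
  set.seed(104)
  pool <- c(vapply(1:40, function(i) randomProteinChars(250), character(1)),
            vapply(1:10, function(i) cassette(sample(7:8, 1)), character(1)))
  arch <- callArchitecture(Biostrings::AAStringSet(
    setNames(pool, paste0("m", seq_along(pool)))))
  withSig <- !is.na(arch$signature_start)
  expect_identical(sum(withSig), 10L)
  expect_true(all(arch$is_rr_tzf[withSig]))
})

test_that("architecture calls are deterministic and order-independent", {
  sim <- generateProteome(defaultCounts(2L), seed = 77)
  arch1 <- callArchitecture(sim$proteins)
  arch2 <- callArchitecture(rev(sim$proteins))
  arch2 <- arch2[match(arch1$protein_id, arch2$protein_id), ]
  rownames(arch2) <- NULL
  expect_identical(arch1, arch2)
})
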