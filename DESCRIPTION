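Package: rrtzf
Title: Detection, Classification and Expression Analysis of Arginine-Rich
    Tandem Zinc-Finger Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the plant RR-TZF protein subfamily: a spacing-grammar
    motif engine for CHCH and tandem CCCH zinc-finger domains, per-protein
    architecture calling, structure-then-homology classification into groups
    I-V and subgroups IIa/IIb, neighbor-joining phylogenies with bootstrap
    support, conservation profiling and consensus-signature derivation from
    multiple alignments, 2^-ddCt relative expression quantification with
    Bonferroni and Dunnett post hoc tests, and seeded synthetic-data
    generators (proteomes with planted architectures, qPCR Ct tables,
    germination counts) that give every stage a ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    multcomp,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
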