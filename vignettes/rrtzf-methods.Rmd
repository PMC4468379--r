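---
title: "Methods: RR-TZF architecture detection, classification and expression statistics"
author: "rrtzf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RR-TZF architecture detection, classification and expression statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrtzf)
```

## The biological problem

Arginine-rich tandem zinc-finger (RR-TZF) proteins are a plant-specific
subgroup of the CCCH zinc-finger family. Their defining architecture is an
arginine-rich region containing a CHCH motif, linked to two tandem CCCH
zinc fingers. Family members regulate seed germination and responses to
salt, cold and drought stress, and the architecture is conserved from
angiosperms down to mosses and green algae. This package implements the
computational side of an RR-TZF family survey: find the architecture in
protein sequences, classify the hits into the family's groups I–V and
subgroups IIa/IIb, summarize conservation as consensus signatures, place
the proteins on a neighbor-joining tree, and analyse the qPCR and
germination experiments that typically accompany such a survey.

## The spacing-grammar model

A zinc-finger domain is chemically defined by a handful of metal-coordinating
residues at constrained distances; everything between them is effectively
free. We therefore model domains as *spacing grammars*: ordered anchors
(literal residues, or bracketed alternative sets) separated by bounded
wildcard spacers. `C-X7-8-C-X5-C-X3-H` reads: cysteine, 7–8 arbitrary
residues, cysteine, 5 residues, cysteine, 3 residues, histidine.

Matching semantics, chosen once and applied everywhere:

* **Exhaustive enumeration.** `scanMotif(mode = "all")` returns *every*
  distinct anchor placement satisfying the bounds, not just one per start
  position. Variable spacers genuinely generate multiple placements, and
  which one is biologically "the" domain is a policy question that belongs
  to the caller (the architecture layer uses leftmost selection), not to
  the scanner.
* **Anchors are literal.** An `X` ambiguity code in a subject sequence can
  occupy a spacer but never satisfies an anchor — anchors are the
  chemically functional residues and an unknown residue cannot be assumed
  to be one.
* `mode = "nonoverlapping"` applies leftmost-greedy selection (earliest
  start; among equal starts, the shortest span), useful for counting
  repeated elements.
* Coordinates are 1-based and inclusive throughout, matching the residue
  numbering convention of the sequence-analysis literature.

The scanner is validated against an independent oracle that enumerates all
spacer-length combinations and tests every start offset — a different
algorithm with the same mathematical definition.

## Architecture calling

`callArchitecture()` composes grammar scans N-terminus to C-terminus:
the leftmost CHCH motif (`C-X5-H-X4-C-X3-H`); then the leftmost generalized
first CCCH domain (`C-X5-20-C-X5-C-X3-H`) starting after it; then the
leftmost second CCCH domain (canonical `C-X5-C-X4-C-X3-H` or one of its two
variants) after that. A protein is called RR-TZF when all three are
simultaneously present. Leftmost-in-order selection mirrors the N-terminal
position of the arginine-rich region relative to the tandem zinc fingers;
no other placement policy is defensible without structural data.

Supporting calls:

* **Spacer class.** The realized first-domain spacer is classified as
  `canonical_7_8`, `nine`, `five`, `long_10_20` (a monocot-associated
  enlargement) or `other`; this drives downstream structure rules.
* **Linker.** The family signature fixes the CCCH1→CCCH2 linker at 16
  residues; the `tandem_ok` flag accepts 10–25 by default because the
  tandem arrangement is described without hard bounds.
* **Extra cysteine.** Most subgroup-IIa proteins carry an additional Cys 12
  residues upstream of the first CHCH cysteine. The offset is a
  configuration knob: the source material is internally inconsistent (−12
  from the first Cys in one place, nine residues upstream of the invariant
  Lys — i.e. −13 — in another); we default to −12 and expose the knob
  rather than resolving the discrepancy.
* **ANK repeats.** With a domain-annotation table, rows labelled `ANK` are
  counted. Without one, a built-in 33-residue ankyrin consensus is slid
  along the sequence and windows matching at least half of its specified
  positions are counted non-overlapping. The consensus detector is a
  pragmatic built-in — the original survey's ANK method is unstated — and
  the annotation table takes precedence when supplied.
* **Signature.** The full family signature
  `KX3CX5HX4CX3HX6RRX6YX4CX7-8CX5CX3HX2FEX3HPX7CX5CX4CFFAH` is strictly
  stronger than the component filter: a signature hit implies the RR-TZF
  call. This implication is property-tested on 10,000 synthetic proteins.
* The hypothesized atypical overlapping domain `C-X12-C-X10-C-X3-H` is
  reported as an annotation flag only.

Proteins with some but not all components are emitted to a separate
excluded report, mirroring how near-miss candidates (likely pseudogenes or
diverged members) are tabulated apart from the family proper.

## Classification

The classifier is structure-then-homology:

1. **Structure rules.** ANK-bearing proteins are group I by definition and
   are excluded from the subgroup comparison, as are proteins with
   non-canonical first spacers or variant second domains.
2. **Homology.** Remaining proteins are compared against labelled exemplars
   by pairwise global-alignment percent identity (BLOSUM62, affine gaps
   10/0.5); identity is identical pairs over alignment columns holding at
   least one residue. Below a 23% floor the protein stays `unassigned`;
   otherwise it takes the group/subgroup of its best exemplar
   (lexicographically smallest id on ties, logged in the output).

Two deliberate substitutions are documented here. "Similarity" is
implemented as percent *identity*: the two are conflated in common usage
and identity is exactly reproducible, while similarity depends on an
arbitrary positives-scoring choice. And the homology step uses pairwise
global alignment rather than similarities read off one large multiple
alignment: pairwise identity is deterministic and independent of the
reference-set composition, whereas MSA-derived similarities change whenever
a sequence is added. `similarityMatrix()` still provides the MSA convention
for users who have an alignment.

The bundled reference set is synthetic (built from the same fixed family
prototypes as the generator, provenance recorded in its metadata) so that
tests and examples run without any database access; real exemplars drop in
as any labelled `AAStringSet`.

## Phylogeny

Distances default to p-distance (1 − identity/100) on the alignment; the
distance model behind the published trees of this family is unstated and
p-distance is the reproducible default, with the distance function exposed
as a parameter. Trees are Saitou–Nei neighbor joining (via ape); negative
branch-length estimates are clamped to zero with a warning, the standard
practice. Bootstrap supports resample alignment columns with replacement
under an explicit seed; support is the percentage of replicate trees
containing the bipartition, and the display filter hides supports below
50%, the usual convention for published trees. NJ correctness is
property-tested: on additive matrices from random trees (n ≤ 8) it must
recover the generating topology and all path distances to 1e-9.

The built-in progressive aligner exists so the pipeline runs end-to-end
without an external aligner: pairwise alignment distances feed an
average-linkage guide tree whose merge matrix drives profile–profile
Needleman–Wunsch (sum-of-pairs BLOSUM62 column scores, linear gap −4 per
column, deterministic diagonal-first tie-break). We use the hclust merge
order rather than an NJ guide tree because an unrooted NJ tree has no
canonical profile-merge order, while the merge matrix does — determinism is
worth more here than marginal alignment quality. It is adequate for the
closely related sequence sets the pipeline produces; for large or highly
divergent real datasets a dedicated aligner should be used and its output
passed to `readAlignment()`.

## Conservation and consensus signatures

`conservationProfile()` reports, per column, the modal residue among
occupied rows (ties broken alphabetically), the identity fraction (modal
count / occupied rows) and the occupancy (occupied rows / all rows).
`consensusSignature()` emits an anchor for every column whose identity
reaches the invariance threshold (default 1.0 — "invariant" means no
disagreement among occupied rows; the threshold is exposed because no
published cutoff exists) and whose occupancy reaches 0.9; maximal runs of
non-conserved columns become spacers. Spacer bounds are computed from
*ungapped per-row residue counts* across the run, not from gapped column
counts: a run where some rows hold 7 residues and others 8 renders as
`X7-8`, exactly reproducing how mixed spacer lengths are written in the
field's notation. Leading and trailing non-conserved runs are trimmed so
the output is itself a valid grammar expression — the derived signature of
a set of conforming sequences re-matches every one of them, which is the
self-consistency property the tests assert.

## Expression and germination statistics

`ddct()` implements 2^−ΔΔCT relative quantification exactly as practised:
technical replicates are averaged first; ΔCT = CT(target) − CT(reference)
per (group, biological replicate); ΔΔCT subtracts the calibrator group's
mean ΔCT; the ratio is 2^−ΔΔCT with amplification efficiency fixed at 2 (no
efficiency-corrected variant). Standard errors are computed on log2 ratios
across biological replicates, matching how expression figures report means
of relative quantification (log2) ± SE. The construction makes the result
invariant to any constant shift of all CTs within a sample — a property
test — and the calibrator's mean ratio is exactly 1 at zero noise.

`anovaPosthoc()` offers the two post hoc procedures used in this
literature. Bonferroni: pairwise t statistics on the pooled ANOVA mean
square with raw p-values multiplied by the contrast count and capped at 1.
Dunnett: many-to-one contrasts against a control, with two-sided p-values
from the equicorrelated multivariate-t distribution (correlation
√(λᵢλⱼ), λᵢ = nᵢ/(nᵢ+n₀)); the multivariate-t integral is evaluated to
~1e-4, so p-values carry that numerical tolerance. Designs with fewer than
two observations per group are refused with a clear error rather than
producing undefined pooled variances. Germination ratios are
arcsine-square-root transformed before ANOVA; expression ratios are
log2-transformed. Significance is flagged at 0.05 and 0.01.

## The synthetic-data generator

The generator gives every stage a ground truth. Proteins are built by
planting an exact signature-conforming cassette — CHCH, first CCCH with the
class's spacer, the 16-residue linker, canonical second CCCH, and the
invariant K/RR/Y/FE/HP residues between them — into random background.
Background composition is uniform over the 20 residues with C and H
down-weighted ×0.3, keeping spurious grammar hits rare (the measured
spurious full-signature rate is asserted < 1%); spacer fillers exclude C/H
entirely so planted coordinates are unambiguous. Class-specific features:
the diagnostic Cys at −12 (extra-Cys class, derived from the same IIa
prototype since extra-Cys carriers are IIa members), three exact ankyrin
consensus copies (group I), first spacers drawn from 10–20 (group V).
Broken-spacing decoys knock exactly one spacer out of bounds (CHCH gap
5→7, CCCH1 spacer →22, or CCCH2 gap 5→6, rotated); random decoys are pure
background.

Planted proteins are mutated copies of fixed per-class prototypes (15%
per-position mutation of filler/background positions only), so family
members are recognizable homologs of the bundled exemplars — which are
built from the same prototypes under a fixed prototype seed (7301). Every
planted protein and broken decoy is *self-verified* against the
architecture caller at generation time (bounded retries), making the truth
coordinates exact by construction; pure-random decoys are not verified
because a chance architecture in background is vanishingly unlikely.
All randomness flows from one explicit seed through a local RNG scope, so
identical seeds give byte-identical FASTA output and the caller's RNG
stream is untouched.

The Ct generator plants log2 fold changes as shifts of the target's
baseline Ct with Gaussian noise (default sd 0.15 cycles, a realistic
qPCR technical noise level) per technical observation, 3 biological × 3
technical replicates by default, matching the replication structure of the
experiments this mirrors; the germination generator draws binomial counts
at planted rates with 80 seeds × 3 replicates, matching 50–100 seed
triplicate assays.

What the generator does *not* emulate: phylogenetic covariance between
sequences (synthetic clades arise by point-mutation radiation from
prototypes, not by evolution along a tree), compositional biases of real
proteomes, indels within domains, biological replicate variance components
distinct from technical noise, and germination overdispersion. Green tests
on synthetic data therefore demonstrate the correctness of the machinery,
not the field performance of the thresholds on real proteomes.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk-scale run as the
package's own choice of study conditions: 5 proteins per class for
recovery, a 10,000-protein pool (including 300 planted and 50 broken
decoys) for the signature-implication property, 200 random additive
matrices (n ≤ 8) for NJ, 100 bootstrap replicates on a 4×2-clade alignment
(1,000 remains the pipeline default, matching published practice), 120
simulated Ct tables across the fold-change grid {−2,−1,0,1,2}, and 1,000
null simulations for the Dunnett type-I error, which must land in
[0.03, 0.07] at nominal 0.05.

Other numerical decisions: molecular weights use ExPASy average residue
masses (average, not monoisotopic, since calculated weights in this
literature are reported on the 0.01-kDa scale); the isoelectric point
bisects the Henderson–Hasselbalch net-charge function on pH [0, 14] to
1e-4 under the EMBOSS pKa set, named in the output metadata because pI is
pKa-set dependent — agreement with other tools is approximate by nature
(compared with a Bjellqvist-set implementation we observe ~0.5 pH
discrepancy on a 384-residue protein, which is expected, and why
cross-tool pI comparisons are treated as sanity checks rather than strict
gates). Degenerate inputs fail fast with named errors: ragged alignments
list the offending rows, missing reference genes name the (group,
replicate), all-gap alignment rows are rejected, and `.` gap symbols are
refused because Clustal dialects disagree on their meaning.

## Known limitations

* The built-in aligner is for convenience, not benchmark-quality MSA.
* Group IV/V taxonomic descriptions (gymnosperm/Solanum, monocot/algae)
  are evidence annotations; no taxonomy database is consulted.
* The ANK consensus detector is heuristic; curated domain annotations are
  preferred when available.
* pI values depend on the pKa set; only the bisection machinery, not
  cross-tool agreement, is guaranteed.
* The classifier's 23% floor and the linker bounds are defaults inherited
  from the family literature, exposed as configuration, and validated only
  on synthetic data here.
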