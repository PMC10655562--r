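---
title: "Detecting intronic AG-gain variants between branchpoint and acceptor"
author: "agscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intronic AG-gain variants between branchpoint and acceptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agscan)
```

## The model

Recognition of an intron's 3' end proceeds from the branchpoint (BP, a single
nucleotide usually 20-40 nt upstream of the acceptor), through the
polypyrimidine tract (PPT), to the canonical acceptor AG (ACC). The scanning
model of acceptor selection implies that the first AG dinucleotide encountered
downstream of the BP competes for acceptor use. Consistent with this, the
stretch from BP to ACC is strongly depleted of AG in the reference genome, and
intronic variants that *gain* an AG there (SNVs, or micro-indels that join,
contain or complete an AG) can create a new acceptor or derail acceptor
recognition altogether, producing misspliced transcripts.

`agscan` operationalises this model. All intron positions are expressed in
3'-anchored coordinates: the last transcribed intron base is -1, so a BP at
-26 lies 26 nt upstream of the intron end. Three zones are delineated per
intron:

* **zone 1** `[BP1+1, ACC-4]` — the PPT, where a gained AG competes directly;
* **zone 2** `[BP2+1, BP1-1]` — the short stretch between the two closest
  branchpoints, for introns with multiple BPs;
* **zone 3** — a fixed 30-nt control window ending immediately 5' of the zone
  anchor (BP1, or BP2 when present).

Within zone 1 the **high-risk** interval `[BP+8, ACC-4]` is where natural
AG/YAG are nearly absent; a gained AG there is the strongest candidate.
Positions -1..-3 (the canonical AG and the conserved pyrimidine at ACC-3) are
excluded: variants touching them are canonical splice-site variants, and
variants hitting the BP nucleotide itself belong to BP-disruption screening,
so both are rejected with explicit reason codes rather than annotated here.

The endpoint convention for zone 3 ("30 nt upstream of the anchor") is read
as `[anchor-30, anchor-1]`, the unique reading that yields exactly 30 nt
abutting the anchor. The high-risk interval is empty whenever `BP1+8 > -4`,
i.e. for BPs at -11 or closer.

## Detection and annotation

Variants are normalized to minimal representation (multi-allelic records
split, shared prefix/suffix trimmed, one anchor base retained for indels) and
evaluated per transcript-intron. Detection builds the ALT-allele sequence of
the intron's 3' region *on the transcribed strand* and reports every AG whose
span includes an edited or inserted base or a deletion junction, and whose
locus was not an AG in the REF alignment. A deletion that merely shortens a
run while leaving an AG at the junction is therefore *not* a gain. Mechanisms
are labelled `snv-new-A`, `snv-new-G`, `del-junction`, `ins-contains-AG`,
`ins-junction` (plus `complex` for multi-nucleotide substitutions, an
extension beyond the three standard indel labels).

Coordinates and distances are measured in the mutant allele's frame, counting
back from the unchanged intron 3' end — splice-site choice operates on the
mutant pre-mRNA, so for zone-1 indels the BP distance reflects post-edit
spacing. Each call carries:

* `AGAIN_BP_DIST` = a_pos - BP (anchoring BP of its zone; zone-2 calls anchor
  to BP2 and are never high-risk),
* `AGAIN_ACC_DIST` = number of intronic nt 3' of the created G — the retained
  intron length if the new acceptor is used,
* `AGAIN_YAG` — whether the base 5' of the created A is a pyrimidine,
* `AGAIN_HIGHRISK` — zone 1 and `BP_DIST >= 8`,
* `AGAIN_SCORE` — an additive 1-5 score: 1 for any AG-gain in zone 1/2, plus
  one point each for zone-1 location, the high-risk tag, YAG creation, and
  acceptor proximity (`ACC_DIST <= 17`, the window holding ~95% of published
  pathogenic calls). The factor weights are arguments of `scoreCall()` and
  can be reconfigured; the default scheme is calibrated so that a zone-1,
  high-risk, YAG, acceptor-proximal call (the validated SPPL2A-class
  geometry) scores the maximal 5, and the published "promising candidate"
  rule (high-risk and score >= 3) is expressible as scan filters
  (`highRiskOnly`, `scoreMin`).

Genomic REF/ALT follow the VCF plus-strand convention throughout; all
sequence logic converts to the transcribed strand first. This discipline
matters: published c.-notation for minus-strand genes is easy to get wrong,
and the package's strand-symmetry test (reverse-complement the genome, flip
the annotation, require byte-identical transcript-space output) guards it.

## Protein outcomes

Two principal missplicing outcomes are modelled, deliberately excluding NMD
prediction, cryptic-site activation and intron retention (observed outcomes,
but not predictable from the variant alone):

1. **New acceptor** — the mature transcript keeps all exons and inserts the
   retained intronic tail. In-frame tails (`ACC_DIST` divisible by 3) insert
   residues; a stop codon inside the tail truncates the product
   (`stop_in_insertion` — note that intron ends are mostly ...TAG/...CAG, and
   TAG read in frame *is* a stop, so AG-gain = stop-gain is a common
   coincidence); other tails frameshift.
2. **Exon skip** — the exon downstream of the intron is omitted. Skipping the
   start-codon exon is gross transcript ablation (`p.0?`, no downstream-ATG
   rescue is attempted); skipping a UTR exon leaves the protein unchanged;
   skipping the stop-codon or terminal exon is emitted with stop-loss flags.

Translation starts at the annotated start codon (which may sit in exon 2 or
later), uses the standard genetic code only, and runs to the first stop.
HGVS p. descriptions are minimal: `p.(=)`, `p.0?`, `p.X#_Y#insZZZ` (trailing
`*` when the insertion ends in a stop), `p.X#_Y#del`, `delins` when a
codon-split exon boundary changes the junctional residue, `p.X#Y`
substitutions, `p.X#*` nonsense, and `p.X#Yfs*N` frameshifts. The test suite
round-trips every emitted description against the mutant protein (frameshift
notation does not encode the substituted tail, so those are checked for
prefix, first changed residue and stop position).

## Reference-genome statistics

`zoneAtlas()` tabulates, per intron, zone intervals, lengths, pyrimidine
fractions and naturally occurring AG/YAG with their distances to the BP.
Supporting operations:

* `agDepletionStat(fracWithAg, fracWithin7)` — the printed depletion
  arithmetic, `frac * (1 - within7)`;
* `probAtLeastOneAG(n, baseProbs)` — exact probability of at least one AG in
  an i.i.d. random n-mer, via the linear recurrence
  `t(k+1) = t(k) - pA*pG*t(k-1)` on the no-AG probability (equivalently a
  two-state transfer matrix on "last base is A"); for uniform bases and
  n = 30 this gives 87%, matched against exhaustive enumeration for n <= 8
  in the tests;
* `agConcealment(seq, dotBracket, agPos)` — whether both bases of an AG are
  base-paired within the given structure. The folding engine is pluggable:
  the bundled `foldMaxPairing()` is a maximum-base-pairing (Nussinov-style)
  folder with Watson-Crick + GU pairs and a minimum hairpin loop of 3. A
  thermodynamic MFE folder produces different structures, so published
  concealment percentages are reproducible only with the original folder;
  what this package guarantees is the concealment *judgment* given any
  dot-bracket structure. We require both pairing partners to lie within the
  supplied sequence; allowing pairing with flanking sequence is a plausible
  alternative reading that would only increase concealment calls.

The genome-wide percentages printed for the human reference (14%/28%/85%
zone occupancy, 76% pyrimidine median and so on) require the real genome and
the full BP database; they are inputs to this package's arithmetic, not
quantities a toy fixture can reproduce, so the tests exercise the operations
on fixtures and the printed arithmetic identities (0.7% = 0.14 x 0.05,
0.28% = 0.07 x 0.04, 87% theoretical) exactly.

## Cohort statistics

`fisherExact2x2()` computes the exact hypergeometric test directly, with the
point-probability two-sided convention of mainstream statistical software
(sum of tables no more probable than observed, 1e-12 relative guard against
floating ties) plus both one-sided alternatives; it is cross-checked against
`stats::fisher.test()` over random tables. For the published YAG x
new-acceptor contingency (229/29 vs 72/20), the printed p = 0.0122 is the
enrichment-direction one-sided value (the two-sided value is 0.0217); the
package therefore exposes sidedness explicitly rather than hard-coding one
convention. `distanceSummary()` uses boundary-inclusive windows
(`BP_DIST >= 8`, `ACC_DIST <= 17`) as printed. `mafCategorize()` applies
singleton (AC = 1) precedence, then common at MAF >= 1% (boundary inclusive),
else rare.

## The synthetic fixture generator

`simulateReference()` emulates the features of real introns that the method
depends on: multi-exon protein-coding transcripts on both strands (stop-free
coding sequence, start codon optionally in exon 2, stop codon in the last
exon); introns with GT donors, YAG acceptor ends and a pyrimidine at ACC-3;
a BP planted at -26 by default (two-BP fixtures add -31, matching the short
median zone-2 spacing); zone-1 sequences drawn pyrimidine-rich at 0.76 and
scrubbed of AG (the AG-exclusion-zone property). These defaults are the
study conditions: -26 sits in the published 20-40 nt BP range and yields the
22-nt median zone-1 length, and 0.76 is the published zone-1 pyrimidine
median. Exon lengths of 36-90 nt and intron lengths of 80-160 nt are chosen
as compact but realistic; explicit per-gene designs override them where a
test needs controlled reading-frame phase.

`simulateVariants()` plants a roster of AG-gain variants of every mechanism
class (adjusting reference bases where a mechanism needs a hosting context,
without breaking the AG-free zone-1 invariant except for the deliberate
AG-preserving-deletion control), plus negative controls that must be rejected
with the right reason codes. Every plant is back-checked against the
resulting sequences independently of the scanner, and a truth table of
expected annotations is emitted; the generator/scanner closure test requires
the scan to reproduce the truth table exactly across 100 seeds. What passing
these tests does *not* show: performance on real genomes with non-canonical
acceptors, overlapping transcripts, BP ambiguity, or base composition beyond
the pyrimidine and AG-suppression knobs — the generator makes no attempt to
model those.

## Numerical and design choices

* Within-sequence positions are 1-based (R convention); intron offsets are
  negative 3'-anchored integers; GTF/VCF are 1-based inclusive externally.
* Branchpoint input is restricted to the `[-100, -3]` acceptor-upstream
  window; per intron, BPs are ranked by proximity to the acceptor with ties
  broken by input order, and ranks 1-2 drive zone building.
* Introns whose reference terminal dinucleotide is not AG (non-canonical or
  U12 acceptors) are kept but flagged, and calls in them carry the flag.
* Transcript-ID versions are stripped when matching MANE-style canonical
  lists.
* A variant creating two AGs at once yields one row per created AG locus.
* Deterministic output order (coordinate, then transcript, then position)
  and seeded generators make every pipeline output a pure function of
  (inputs, configuration, seed).

## Problem sizes used in the tests

The suite runs entirely on generated fixtures: oracle equivalence on 10,000
random variants over a 6-gene genome against a full-intron-rebuild oracle,
truth-table closure over 100 seeds of a 5-gene fixture, strand-symmetry on
4-gene fixtures, and exhaustive enumeration up to 8-mers for the AG
probability. These sizes were chosen to exercise every mechanism and edge
class densely while keeping the suite comfortably fast on one CPU.

## Limitations

Zone-2 calls anchor their BP distance to the second branchpoint and are never
tagged high-risk; whether a single reported BP distance should instead always
anchor to BP1 is ambiguous in the field's reporting conventions. The score's
factor set beyond its calibration points (range 1-5, maximal for the
SPPL2A-class geometry, >= 3 as the prioritization cut) is a declared default,
overridable via `scoreCall()` weights. Selenocysteine recoding and
non-standard genetic codes are unsupported. No attempt is made to predict
which of the two missplicing outcomes will dominate — both are emitted as
hypotheses for experimental validation.
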