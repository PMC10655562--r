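# agscan

Detection and annotation of intronic **AG-gain variants** between the
splicing branchpoint (BP) and the canonical splice acceptor (ACC), for human
geneticists triaging intronic variants from WES/WGS VCFs.

## The problem and the method

The 3' end of an intron is recognised in order: branchpoint, polypyrimidine
tract (PPT), acceptor AG. Because acceptor selection scans for the first AG
downstream of the BP, the `[BP, ACC]` stretch is strongly depleted of AG in
the reference genome, and a variant that *introduces* an AG there — an SNV,
a deletion joining an A and a G, or an insertion carrying or completing an
AG — can hijack acceptor choice (new acceptor site, retaining the intronic
tail in the mRNA) or derail 3'-end recognition (exon skipping).

With intron positions counted back from the 3' end (last base = -1) and the
first/second branchpoints BP1/BP2, `agscan`:

* delineates **zone 1** `[BP1+1, ACC-4]`, **zone 2** `[BP2+1, BP1-1]` and the
  30-nt control **zone 3** per intron, plus the **high-risk** interval
  `[BP1+8, ACC-4]` where natural AG/YAG are nearly absent;
* scans VCF variants on the transcribed strand of the mutant allele and
  reports every newly created AG with mechanism class (`snv-new-A`,
  `snv-new-G`, `del-junction`, `ins-contains-AG`, `ins-junction`), distances
  `BP_DIST = a - BP` and `ACC_DIST` (= retained-intron length if the new
  acceptor is used), YAG context, the high-risk tag, and an additive 1-5
  priority score;
* predicts the protein products of the two principal missplicing outcomes —
  new acceptor and skipping of the next exon — with HGVS p. nomenclature
  (frameshifts, stop-in-insertion truncations, start-codon ablation `p.0?`);
* provides the reference-genome zone statistics (pyrimidine content, natural
  AG/YAG scan, the depletion arithmetic `f_AG x (1 - f_within7)`, the exact
  probability `1 - t(n)` of at least one AG in a random n-mer via
  `t(k+1) = t(k) - pA pG t(k-1)`, and stem-concealment of AGs in dot-bracket
  structures with a bundled Nussinov-style folder);
* computes cohort summaries (exact Fisher 2x2 tests, distance-window shares,
  singleton/rare/common MAF categories);
* generates seeded synthetic fixtures (FASTA + GTF + BP table + VCF + truth
  table) so the entire pipeline is testable without downloads.

## Worked example

```r
library(agscan)

fix <- simulateReference(fixtureSpec(nGenes = 2, seed = 1))  # toy genome
vs  <- simulateVariants(fix, defaultRoster()[1:4, ])         # plant variants
db  <- fixtureDb(vs$fix)                                     # intron database
vcf <- tempfile(fileext = ".vcf"); writeVcfLines(vs$vcfLines, vcf)
tab <- scanVariants(db, vcf)
tab[, c("ID", "VAR_TYPE", "TRANSCRIPT_IVS", "AGAIN_ZONE", "AGAIN_YAG",
        "AGAIN_BP_DIST", "AGAIN_ACC_DIST", "AGAIN_HIGHRISK", "AGAIN_SCORE")]
#>      ID       VAR_TYPE TRANSCRIPT_IVS AGAIN_ZONE AGAIN_YAG AGAIN_BP_DIST
#> 1  snvA            snv       TX1_IVS1     ZONE 1       YES            10
#> 2  snvG            snv       TX1_IVS2     ZONE 1        NO            12
#> 3 insAG 2 nt-insertion       TX2_IVS2     ZONE 1       YES            14
#> 4  delj  2 nt-deletion       TX2_IVS1     ZONE 1       YES            10
#>   AGAIN_ACC_DIST AGAIN_HIGHRISK AGAIN_SCORE
#> 1             14            YES           5
#> 2             12            YES           4
#> 3             12            YES           5
#> 4             12            YES           5
```

Each row is one AG-gain in one transcript's intron: e.g. row 1 is an SNV
creating a YAG 10 nt downstream of the BP and 14 nt from the acceptor —
inside the high-risk region, and scoring the maximal 5 (zone 1 + high-risk +
YAG + acceptor-proximal + base point). The protein columns give both
missplicing hypotheses, e.g.

```r
tab[, c("ID", "HGVS_NEW_ACC", "HGVS_EXON_SKIP")]
#>      ID                 HGVS_NEW_ACC   HGVS_EXON_SKIP
#> 1  snvA               p.Tyr10Leufs*5   p.Tyr10Serfs*4
#> 2  snvG   p.Pro34_Arg35insThrSerPhe* p.Arg35_Glu42del
#> 3 insAG p.Cys39_Asp40insLeuLeuValSer         p.Cys39*
#> 4  delj p.Thr15_Phe16insTyrLysTyrArg p.Phe16_Cys39del
```

— row 2's new acceptor inserts three residues ending in a stop
(`stop-in-insertion`: intron ends are mostly YAG, and TAG in frame is a stop
codon), while its exon-skip alternative is an in-frame deletion.

Headline statistics:

```r
signif(fisherExact2x2(229, 29, 72, 20, alternative = "greater"), 3)
#> [1] 0.0122      # YAG enrichment among new-acceptor-forming variants
round(100 * probAtLeastOneAG(30))
#> [1] 87          # chance of an AG in a random 30-mer
agDepletionStat(0.14, 0.95)
#> [1] 0.007       # introns with an AG beyond BP+7
```

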