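Package: agscan
Title: Detection of Intronic AG-Gain Variants Between Branchpoint and Splice Acceptor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide detection and annotation of intronic variants that
    create AG dinucleotides between the splicing branchpoint (BP) and the
    canonical splice acceptor (ACC). Delineates the three BP-anchored analysis
    zones of each intron, scans VCF variants for SNV and micro-indel AG-gain
    mechanisms, annotates distance to BP/ACC, YAG context, a high-risk tag for
    the [BP+8, ACC-4] region and a 1-5 priority score, and predicts the
    protein-level products of the two principal missplicing outcomes (use of
    the new acceptor site and complete skipping of the next exon) with HGVS
    p. nomenclature. Includes reference-genome zone statistics (pyrimidine
    content, natural AG/YAG occurrence, depletion arithmetic, theoretical AG
    probability, structural concealment), cohort-level summaries, and a seeded
    synthetic fixture generator producing FASTA/GTF/branchpoint/VCF test data
    with machine-readable truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'agscan-package.R'
    'annotationDb.R'
    'cli.R'
    'cohortStats.R'
    'hgvs.R'
    'protein.R'
    'simulate.R'
    'variantScan.R'
    'zones.R'
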