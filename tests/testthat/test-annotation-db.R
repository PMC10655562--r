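writeGtf <- function(lines) {
  p <- tempfile(fileext = ".gtf")
  writeLines(lines, p)
  p
}

gtfLine <- function(chrom, type, start, end, strand, tx, ttype = "protein_coding",
                    tag = "basic", level = "2") {
  sprintf(paste0('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "G_%s"; transcript_id "%s"; ',
                 'gene_name "G_%s"; transcript_type "%s"; tag "%s"; level "%s";'),
          chrom, type, start, end, strand, tx, tx, tx, ttype, tag, level)
}

test_that("GTF loader applies the protein-coding/basic/level filters", {
  mk <- function(tx, ttype = "protein_coding", level = "2") {
    c(gtfLine("chr1", "transcript", 1, 300, "+", tx, ttype, level = level),
      gtfLine("chr1", "exon", 1, 100, "+", tx, ttype, level = level),
      gtfLine("chr1", "exon", 201, 300, "+", tx, ttype, level = level))
  }
  p <- writeGtf(c(mk("T1"), mk("T2"), mk("T3", level = "3")))
  txs <- loadGeneModels(p)
  expect_setequal(names(txs), c("T1", "T2"))

  p2 <- writeGtf(c(mk("TC"), mk("TL", ttype = "lncRNA")))
  expect_named(loadGeneModels(p2), "TC")
})

test_that("malformed GTF lines are reported with their line number", {
  p <- writeGtf(c(gtfLine("chr1", "exon", 1, 100, "+", "T1"), "chr1\tbroken"))
  expect_error(loadGeneModels(p), "line 2")
})

test_that("minus-strand exons come back in transcription order", {
  lines <- c(gtfLine("chr1", "transcript", 1, 500, "-", "TM"),
             gtfLine("chr1", "exon", 1, 100, "-", "TM"),
             gtfLine("chr1", "exon", 201, 300, "-", "TM"),
             gtfLine("chr1", "exon", 401, 500, "-", "TM"))
  txs <- loadGeneModels(writeGtf(lines))
  ex <- exons(txs$TM)
  expect_equal(IRanges::start(ex), c(401L, 201L, 1L))
  iv <- extractIntrons(txs$TM)
  # intron 1 is the most 3'-genomic gap on the minus strand
  expect_equal(iv$start, c(301L, 101L))
  expect_equal(iv$end, c(400L, 200L))
  expect_equal(iv$intron_index, c(1L, 2L))
})

test_that("intron derivation numbers gaps in transcription direction", {
  plus <- new("TranscriptModel", transcriptId = "P", geneSymbol = "P",
              chrom = "chr1", strand = "+",
              exons = IRanges::IRanges(c(1, 201, 401), c(100, 300, 500)))
  iv <- extractIntrons(plus)
  expect_equal(iv$start, c(101L, 301L))
  expect_equal(iv$end, c(200L, 400L))

  single <- new("TranscriptModel", transcriptId = "S", geneSymbol = "S",
                chrom = "chr1", strand = "+",
                exons = IRanges::IRanges(1, 100))
  expect_equal(nrow(extractIntrons(single)), 0L)

  two <- new("TranscriptModel", transcriptId = "D", geneSymbol = "D",
             chrom = "chr1", strand = "+",
             exons = IRanges::IRanges(c(1, 201), c(100, 300)))
  expect_equal(nrow(extractIntrons(two)), 1L)
})

test_that("branchpoint loading filters, ranks and maps offsets", {
  one <- loadBranchpoints(data.frame(t = "TX", i = 1L, o = -26L))
  expect_equal(one$rank, 1L)

  multi <- loadBranchpoints(data.frame(t = "TX", i = 1L, o = c(-40L, -26L, -31L)))
  expect_equal(multi$offset[multi$rank == 1L], -26L)
  expect_equal(multi$offset[multi$rank == 2L], -31L)
  expect_equal(multi$offset[multi$rank == 3L], -40L)  # retained but unranked for zones

  expect_equal(nrow(loadBranchpoints(data.frame(t = "TX", i = 1L, o = -102L))), 0L)
  expect_equal(nrow(loadBranchpoints(data.frame(t = "TX", i = 1L, o = -2L))), 0L)
})

test_that("BED branchpoints are mapped into anchored offsets per strand", {
  introns <- data.frame(transcript_id = c("TP", "TM"), intron_index = 1L,
                        chrom = "chr1", start = c(101L, 101L), end = c(200L, 200L),
                        strand = c("+", "-"), length = 100L)
  bed <- data.frame(chrom = "chr1", start = c(174L, 125L), end = c(175L, 126L),
                    name = c("TP|1|1", "TM|1|1"), score = 0L,
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  got <- loadBranchpoints(bed, introns)
  expect_equal(got$offset[got$transcript_id == "TP"], -26L)
  expect_equal(got$offset[got$transcript_id == "TM"], -26L)

  badStrand <- transform(bed[1, ], strand = "-")
  expect_warning(out <- loadBranchpoints(badStrand, introns), "strand mismatch")
  expect_equal(nrow(out), 0L)
})

test_that("canonical selection strips versions and handles empty intersections", {
  txs <- list()
  for (id in c("ENST0001.4", "ENST0002.1", "ENST0003.2")) {
    txs[[id]] <- new("TranscriptModel", transcriptId = id, geneSymbol = id,
                     chrom = "chr1", strand = "+",
                     exons = IRanges::IRanges(1, 100))
  }
  flagged <- selectCanonical(txs, c("ENST0001", "ENST0003"))
  expect_equal(vapply(flagged, function(t) t@isCanonical, logical(1)),
               c(ENST0001.4 = TRUE, ENST0002.1 = FALSE, ENST0003.2 = TRUE))
  expect_length(selectCanonical(txs, c("ENST0001"), mode = "canonical"), 1L)
  expect_warning(selectCanonical(txs, "ENST9999"), "empty intersection")
  expect_error(selectCanonical(txs, character(), mode = "canonical"),
               "all-transcript mode")
})

test_that("the 3'-anchored coordinate map is a bijection on both strands", {
  for (strand in c("+", "-")) {
    start <- 501L; end <- 620L; L <- end - start + 1L
    ks <- seq_len(L)
    g <- anchoredToGenomic(start, end, strand, -ks)
    expect_equal(sort(g), start:end)
    expect_equal(genomicToAnchored(start, end, strand, g), -ks)
  }
})

test_that("database assembly caches sequences and flags non-AG acceptors", {
  fx <- plantedFixture(seed = 11)
  db <- fx$db
  m <- S4Vectors::mcols(introns(db))
  expect_true(all(m$acceptor_ag))
  expect_true(all(substr(m$seq, nchar(m$seq) - 1L, nchar(m$seq)) == "AG"))
  expect_true(all(substr(m$seq, 1L, 2L) == "GT"))
  # zone table covers every intron with the planted branchpoint
  zt <- zoneTable(db)
  expect_true(all(zt$bp1 == -26L))
  expect_equal(nrow(zt), length(introns(db)))

  # break one acceptor and expect the warning + flag
  fix <- simulateReference(fixtureSpec(nGenes = 2, seed = 3))
  fix <- agscan:::fixtureSetBase(fix, 1L, 1L, -1L, "T")
  expect_warning(db2 <- fixtureDb(fix), "terminal AG")
  m2 <- S4Vectors::mcols(introns(db2))
  expect_equal(sum(!m2$acceptor_ag), 1L)
})

test_that("reverse-complementing the fixture leaves intron-space annotation unchanged", {
  fix <- simulateReference(fixtureSpec(nGenes = 4, seed = 5))
  db1 <- fixtureDb(fix)
  db2 <- fixtureDb(revCompFixture(fix))
  key <- function(db) {
    m <- S4Vectors::mcols(introns(db))
    o <- order(m$transcript_id, m$intron_index)
    data.frame(tx = m$transcript_id[o], ivs = m$intron_index[o],
               len = GenomicRanges::width(introns(db))[o], seq = m$seq[o])
  }
  expect_identical(key(db1), key(db2))
  expect_identical(branchpoints(db1), branchpoints(db2))
  zt1 <- zoneTable(db1); zt2 <- zoneTable(db2)
  expect_identical(zt1[order(zt1$transcript_id, zt1$intron_index), ],
                   zt2[order(zt2$transcript_id, zt2$intron_index), ])
})

test_that("GTF/FASTA round-trip through files matches the in-memory database", {
  fix <- simulateReference(fixtureSpec(nGenes = 3, seed = 9))
  dir <- tempfile(); paths <- writeFixture(fix, dir)
  db1 <- buildSpliceDb(paths[["genome"]], paths[["gtf"]], paths[["bp"]],
                       canonical = paths[["canonical"]])
  db2 <- fixtureDb(fix)
  m1 <- S4Vectors::mcols(introns(db1)); m2 <- S4Vectors::mcols(introns(db2))
  o1 <- order(m1$transcript_id, m1$intron_index)
  o2 <- order(m2$transcript_id, m2$intron_index)
  expect_identical(m1$seq[o1], m2$seq[o2])
  for (id in names(transcripts(db2))) {
    t1 <- transcripts(db1)[[id]]; t2 <- transcripts(db2)[[id]]
    expect_identical(IRanges::start(exons(t1)), IRanges::start(exons(t2)))
    expect_identical(t1@cdsStart, t2@cdsStart)
    expect_identical(t1@cdsEnd, t2@cdsEnd)
  }
})
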