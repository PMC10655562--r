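test_that("VCF records normalize to minimal per-ALT variants", {
  df <- data.frame(CHROM = "chr1", POS = 100L, ID = "v", REF = "A", ALT = "G,T")
  nv <- normalizeVariants(df)
  expect_equal(nrow(nv), 2L)
  expect_true(all(nv$var_type == "snv"))

  del <- normalizeVariants(data.frame(CHROM = "chr1", POS = 100L, ID = "d",
                                      REF = "CAG", ALT = "CG"))
  expect_equal(del$pos, 100L)            # anchor kept
  expect_equal(del$var_type, "1 nt-deletion")
  expect_equal(agscan:::coreEdit(100L, "CAG", "CG")$gs, 101L)

  ins <- normalizeVariants(data.frame(CHROM = "chr1", POS = 100L, ID = "i",
                                      REF = "C", ALT = "CAG"))
  expect_equal(ins$var_type, "2 nt-insertion")

  expect_warning(eq <- normalizeVariants(
    data.frame(CHROM = "chr1", POS = 1L, ID = "x", REF = "A", ALT = "A")),
    "REF equals ALT")
  expect_equal(nrow(eq), 0L)
  expect_warning(sym <- normalizeVariants(
    data.frame(CHROM = "chr1", POS = 1L, ID = "x", REF = "A", ALT = "<DEL>")),
    "symbolic")
  expect_equal(nrow(sym), 0L)
})

test_that("distance arithmetic matches the published worked examples", {
  expect_equal(computeDistances(-8L, -7L, -26L), list(bpDist = 18L, accDist = 6L))
  expect_equal(computeDistances(-10L, -9L, -26L), list(bpDist = 16L, accDist = 8L))
  expect_equal(computeDistances(-25L, -24L, -26L)$bpDist, 1L)
  expect_error(computeDistances(-27L, -26L, -26L), "internal")
})

test_that("high-risk classification uses the [BP+8, ACC-4] rule", {
  expect_true(classifyRisk("ZONE 1", 18L))
  expect_false(classifyRisk("ZONE 1", 5L))
  expect_true(classifyRisk("ZONE 1", 8L))    # inclusive boundary
  expect_false(classifyRisk("ZONE 2", 20L))
})

test_that("the score scheme is bounded and monotone in every factor", {
  expect_equal(scoreCall("ZONE 1", TRUE, TRUE, 6L), 5L)    # SPPL2A-like
  expect_equal(scoreCall("ZONE 2", FALSE, FALSE, 30L), 1L)
  combos <- expand.grid(zone = c("ZONE 1", "ZONE 2"), hr = c(TRUE, FALSE),
                        yag = c(TRUE, FALSE), prox = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  sc <- function(r) scoreCall(r$zone, r$hr, r$yag, if (r$prox) 10L else 30L)
  for (i in seq_len(nrow(combos))) {
    s <- sc(combos[i, ])
    expect_true(s >= 1L && s <= 5L)
    for (f in c("hr", "yag", "prox")) {
      up <- combos[i, ]; up[[f]] <- TRUE
      dn <- combos[i, ]; dn[[f]] <- FALSE
      expect_gte(sc(up), sc(dn))
    }
    z1 <- combos[i, ]; z1$zone <- "ZONE 1"
    z2 <- combos[i, ]; z2$zone <- "ZONE 2"
    expect_gte(sc(z1), sc(z2))
  }
})

test_that("published variant geometries are recovered from planted fixtures", {
  fx <- paperGeometryFixture()
  tab <- scanVariants(fx$db, vcfLinesToDf(fx$vs$vcfLines))
  get <- function(id) tab[tab$ID == id, ]
  expect_equal(get("VAR1")$AGAIN_BP_DIST, 16L)
  expect_equal(get("VAR1")$AGAIN_ACC_DIST, 8L)   # 8-nt retention
  expect_equal(get("VAR2")$AGAIN_BP_DIST, 5L)
  expect_equal(get("VAR2")$AGAIN_HIGHRISK, "NO")
  expect_equal(get("VAR3")$AGAIN_BP_DIST, 21L)
  expect_equal(get("VAR3")$AGAIN_HIGHRISK, "YES")
  expect_equal(get("VAR4")$AGAIN_BP_DIST, 6L)
  expect_equal(get("VAR4")$AGAIN_HIGHRISK, "NO")
  sp <- get("SPPL2A")
  expect_equal(sp$AGAIN_BP_DIST, 18L)
  expect_equal(sp$AGAIN_ACC_DIST, 6L)
  expect_equal(sp$AGAIN_SCORE, 5L)
  # VAR3 creates a TAG (pyrimidine T immediately 5' of the AG)
  db <- fx$db
  m <- S4Vectors::mcols(introns(db))
  v3 <- get("VAR3")
  expect_equal(v3$AGAIN_YAG, "YES")
})

test_that("an SNV creating AA and an AG-preserving deletion yield no call", {
  fx <- plantedFixture(seed = 42)
  truth <- fx$vs$truth
  tab <- scanVariants(fx$db, vcfLinesToDf(fx$vs$vcfLines), protein = FALSE)
  negs <- truth[!truth$expect_call, ]
  expect_false(any(tab$ID %in% negs$label))
  rej <- attr(tab, "rejected")
  expect_equal(rej$reason[rej$id == "neg_bp"], "BP-variant (BPHunter scope)")
  expect_equal(rej$reason[rej$id == "neg_acc"], "canonical-ACC variant")
})

test_that("scanning a planted VCF reproduces the truth table exactly", {
  fx <- plantedFixture(seed = 42)
  truth <- fx$vs$truth[fx$vs$truth$expect_call, ]
  tab <- scanVariants(fx$db, vcfLinesToDf(fx$vs$vcfLines))
  expect_equal(nrow(tab), nrow(truth))
  mg <- merge(truth, tab, by.x = "label", by.y = "ID")
  expect_equal(nrow(mg), nrow(truth))
  expect_equal(mg$transcript_ivs, mg$TRANSCRIPT_IVS)
  expect_equal(mg$zone, mg$AGAIN_ZONE)
  expect_equal(mg$mechanism, mg$MECHANISM)
  expect_equal(mg$a_pos, mg$A_POS)
  expect_equal(mg$g_pos, mg$G_POS)
  expect_equal(ifelse(mg$yag, "YES", "NO"), mg$AGAIN_YAG)
  expect_equal(mg$bp_dist, mg$AGAIN_BP_DIST)
  expect_equal(mg$acc_dist, mg$AGAIN_ACC_DIST)
  expect_equal(ifelse(mg$high_risk, "YES", "NO"), mg$AGAIN_HIGHRISK)
  expect_equal(mg$score, mg$AGAIN_SCORE)
})

test_that("score and high-risk filters restrict the output", {
  fx <- plantedFixture(seed = 42)
  vdf <- vcfLinesToDf(fx$vs$vcfLines)
  all <- scanVariants(fx$db, vdf, protein = FALSE)
  hr <- scanVariants(fx$db, vdf, protein = FALSE, highRiskOnly = TRUE)
  expect_true(all(hr$AGAIN_HIGHRISK == "YES"))
  s4 <- scanVariants(fx$db, vdf, protein = FALSE, scoreMin = 5L)
  expect_true(all(s4$AGAIN_SCORE >= 5L))
  expect_true(nrow(s4) <= nrow(all))
})

test_that("empty VCF input yields a header-only table", {
  db <- plantedFixture(seed = 42)$db
  empty <- data.frame(CHROM = character(), POS = integer(), ID = character(),
                      REF = character(), ALT = character())
  tab <- scanVariants(db, empty)
  expect_equal(nrow(tab), 0L)
  expect_true(all(agscan:::scanColumns %in% names(tab)))
  p <- tempfile(fileext = ".tsv")
  writeScanTsv(tab, p)
  expect_equal(readLines(p), paste(agscan:::scanColumns, collapse = "\t"))
})

test_that("reference mismatches are row-level errors, missing contigs fatal", {
  fx <- plantedFixture(seed = 42)
  truth <- fx$vs$truth[fx$vs$truth$expect_call, ][1, ]
  bad <- data.frame(CHROM = truth$chrom, POS = truth$pos, ID = "bad",
                    REF = chartr("ACGT", "GTAC", truth$ref), ALT = truth$alt)
  tab <- scanVariants(fx$db, bad, protein = FALSE)
  expect_equal(nrow(tab), 0L)
  expect_true("ref-mismatch" %in% attr(tab, "rejected")$reason)
  expect_error(scanVariants(fx$db,
    data.frame(CHROM = "chrMISSING", POS = 1L, ID = "x", REF = "A", ALT = "G")),
    "missing contig")
})

test_that("a VCF file on disk scans identically to the in-memory table", {
  fx <- plantedFixture(seed = 42)
  p <- tempfile(fileext = ".vcf")
  writeVcfLines(fx$vs$vcfLines, p)
  t1 <- scanVariants(fx$db, p, protein = FALSE)
  t2 <- scanVariants(fx$db, vcfLinesToDf(fx$vs$vcfLines), protein = FALSE)
  attr(t1, "rejected") <- attr(t2, "rejected") <- NULL
  expect_identical(t1, t2)
})

test_that("a variant creating two AGs emits one row per created locus", {
  # insertion of AGAG creates two AG loci inside the inserted sequence
  fix <- simulateReference(fixtureSpec(nGenes = 1, seed = 13, strands = "+"))
  db <- fixtureDb(fix)
  g <- agscan:::fixtureAnchored2G(fix, 1L, 1L, -14L)
  chromSeq <- as.character(fix$genome[["chr1"]])
  anchor <- substr(chromSeq, g, g)
  tab <- scanVariants(db, data.frame(CHROM = "chr1", POS = g, ID = "dbl",
                                     REF = anchor, ALT = paste0(anchor, "AGAG")),
                      protein = FALSE)
  tab <- tab[tab$TRANSCRIPT_IVS == "TX1_IVS1", ]
  expect_equal(nrow(tab), 2L)
  expect_equal(anyDuplicated(tab[, c("A_POS", "G_POS")]), 0L)
})

test_that("the scanner agrees with the full-intron-rebuild oracle", {
  fx <- plantedFixture(seed = 77, nGenes = 4)
  rv <- randomVariantRoster(fx$db, 400, seed = 78)
  for (i in seq_len(nrow(rv)))
    expectOracleAgreement(fx$db, rv$txid[i], rv$ivs[i], rv$pos[i],
                          rv$ref[i], rv$alt[i])
  succeed()
})

test_that("scan annotation is strand-symmetric in transcript space", {
  fix <- simulateReference(fixtureSpec(nGenes = 4, seed = 55))
  vs1 <- simulateVariants(fix, defaultRoster())
  fix2 <- revCompFixture(simulateReference(fixtureSpec(nGenes = 4, seed = 55)))
  vs2 <- simulateVariants(fix2, defaultRoster())
  t1 <- scanVariants(fixtureDb(vs1$fix), vcfLinesToDf(vs1$vcfLines))
  t2 <- scanVariants(fixtureDb(vs2$fix), vcfLinesToDf(vs2$vcfLines))
  cols <- setdiff(names(t1), c("CHROM", "POS", "REF", "ALT"))
  o1 <- t1[order(t1$ID), cols]; rownames(o1) <- NULL
  o2 <- t2[order(t2$ID), cols]; rownames(o2) <- NULL
  expect_identical(o1, o2)
})
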