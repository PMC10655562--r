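#' @include AllClasses.R
NULL

#' Specification for a synthetic splice fixture
#'
#' Defines the study conditions the generator emulates: multi-exon
#' protein-coding transcripts on both strands, branchpoints planted at a
#' fixed offset upstream of the acceptor (default -26, the cohort median
#' neighbourhood), pyrimidine-rich AG-depleted zone-1 sequences (default
#' pyrimidine probability 0.76, the published zone-1 median), and canonical
#' GT..AG intron ends with a pyrimidine at ACC-3.
#'
#' @param nGenes number of genes (one transcript each, one contig per gene).
#' @param seed RNG seed; identical seeds give byte-identical fixtures.
#' @param strands strand assignment, recycled over genes.
#' @param nIntronsRange,exonLenRange,intronLenRange sampling ranges.
#' @param bp1 first-branchpoint offset (negative, 3'-anchored).
#' @param bp2 optional second-branchpoint offset (more negative than `bp1`).
#' @param pyrimidineProb zone-1 pyrimidine probability.
#' @param suppressZone1Ag remove every AG from reference zone-1 sequences.
#' @param genes optional list of explicit per-gene designs, each a list with
#'   `strand`, `exonLens`, `intronLens`, `utr5` (overrides the sampling).
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nGenes = 5L, seed = 1L, strands = c("+", "-"),
                        nIntronsRange = c(2L, 3L), exonLenRange = c(36L, 90L),
                        intronLenRange = c(80L, 160L), bp1 = -26L,
                        bp2 = NA_integer_, pyrimidineProb = 0.76,
                        suppressZone1Ag = TRUE, genes = NULL) {
  anchor <- if (is.na(bp2)) bp1 else bp2
  if (intronLenRange[1L] < -anchor + 6L)
    stop("infeasible spec: introns shorter than the branchpoint region")
  structure(list(nGenes = nGenes, seed = seed, strands = strands,
                 nIntronsRange = nIntronsRange, exonLenRange = exonLenRange,
                 intronLenRange = intronLenRange, bp1 = as.integer(bp1),
                 bp2 = as.integer(bp2), pyrimidineProb = pyrimidineProb,
                 suppressZone1Ag = suppressZone1Ag, genes = genes),
            class = "FixtureSpec")
}

#' Generate a toy genome, gene annotation and branchpoint table
#'
#' @param spec a [fixtureSpec()].
#' @return an `AgFixture` list: `genome` (DNAStringSet), `gtfLines`,
#'   `bp` (offset table), `canonical`, `genes` (structural metadata), `spec`.
#' @export
simulateReference <- function(spec) {
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  rnd <- function(n) sample(bases, n, replace = TRUE)
  senseCodons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

  genomeSeqs <- character(spec$nGenes)
  genes <- vector("list", spec$nGenes)
  gtf <- character()
  bpRows <- list()

  for (g in seq_len(spec$nGenes)) {
    design <- if (!is.null(spec$genes) && g <= length(spec$genes)) spec$genes[[g]] else NULL
    strand <- if (!is.null(design)) design$strand
              else spec$strands[((g - 1L) %% length(spec$strands)) + 1L]
    nIv <- if (!is.null(design)) length(design$intronLens)
           else sample(spec$nIntronsRange[1L]:spec$nIntronsRange[2L], 1L)
    nEx <- nIv + 1L
    exLens <- if (!is.null(design)) design$exonLens
              else sample(spec$exonLenRange[1L]:spec$exonLenRange[2L], nEx, replace = TRUE)
    ivLens <- if (!is.null(design)) design$intronLens
              else sample(spec$intronLenRange[1L]:spec$intronLenRange[2L], nIv, replace = TRUE)
    utr5 <- if (!is.null(design)) design$utr5 else sample(6:12, 1L)
    M <- sum(exLens)
    utr3 <- sample(6:12, 1L)
    cdsLen <- M - utr5 - utr3
    utr3 <- utr3 + cdsLen %% 3L
    cdsLen <- cdsLen - cdsLen %% 3L
    stopifnot(cdsLen >= 9L)
    inner <- sample(senseCodons, cdsLen / 3L - 2L, replace = TRUE)
    mrna <- c(rnd(utr5), strsplit(paste0("ATG", paste(inner, collapse = ""), "TAA"),
                                  "")[[1L]], rnd(utr3))
    # pairwise codon joins can form ATG..TAA only within codons; inner codons are
    # sense codons so the spliced CDS is stop-free by construction

    iseqs <- lapply(ivLens, function(L)
      makeIntron(L, spec$bp1, spec$bp2, spec$pyrimidineProb,
                 spec$suppressZone1Ag, bases))

    # unspliced transcript (transcription direction)
    exStartT <- integer(nEx); exEndT <- integer(nEx)
    ivStartT <- integer(nIv); ivEndT <- integer(nIv)
    uns <- character(0L); t <- 0L
    exCum <- cumsum(exLens)
    for (i in seq_len(nEx)) {
      sIdx <- if (i == 1L) 1L else exCum[i - 1L] + 1L
      exStartT[i] <- t + 1L
      uns <- c(uns, mrna[sIdx:exCum[i]])
      t <- t + exLens[i]; exEndT[i] <- t
      if (i <= nIv) {
        ivStartT[i] <- t + 1L
        uns <- c(uns, iseqs[[i]])
        t <- t + ivLens[i]; ivEndT[i] <- t
      }
    }
    Lg <- t
    pad1 <- rnd(120L); pad2 <- rnd(120L)
    geneStart <- 121L; geneEnd <- 120L + Lg
    chromT <- c(pad1, uns, pad2)
    chromSeq <- if (strand == "+") paste(chromT, collapse = "")
      else as.character(Biostrings::reverseComplement(
             Biostrings::DNAString(paste(chromT, collapse = ""))))
    chrom <- paste0("chr", g)
    genomeSeqs[g] <- chromSeq
    Lc <- nchar(chromSeq)

    mapT2G <- function(t) if (strand == "+") geneStart + t - 1L else Lc - (geneStart + t - 1L) + 1L
    gInt <- function(a, b) sort(c(mapT2G(a), mapT2G(b)))

    txid <- sprintf("TX%d", g); sym <- sprintf("GENE%d", g)
    attrs <- paste0('gene_id "', sym, '"; transcript_id "', txid,
                    '"; gene_name "', sym,
                    '"; transcript_type "protein_coding"; tag "basic"; level "2";')
    feat <- function(type, a, b) {
      gi <- gInt(a, b)
      sprintf("%s\tagscan_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, type, gi[1L], gi[2L], strand, attrs)
    }
    gtf <- c(gtf, feat("gene", 1L, Lg), feat("transcript", 1L, Lg))
    for (i in seq_len(nEx)) gtf <- c(gtf, feat("exon", exStartT[i], exEndT[i]))
    # spliced -> unspliced coordinate
    s2t <- function(s) {
      i <- findInterval(s, c(0L, exCum) + 1L)
      exStartT[i] + (s - (if (i == 1L) 0L else exCum[i - 1L])) - 1L
    }
    cdsS <- utr5 + 1L; cdsE <- utr5 + cdsLen          # spliced coords incl stop
    for (i in seq_len(nEx)) {
      sA <- max(cdsS, if (i == 1L) 1L else exCum[i - 1L] + 1L)
      sB <- min(cdsE - 3L, exCum[i])
      if (sA <= sB) gtf <- c(gtf, feat("CDS", s2t(sA), s2t(sB)))
    }
    gtf <- c(gtf, feat("stop_codon", s2t(cdsE - 2L), s2t(cdsE)))

    for (i in seq_len(nIv)) {
      bpRows[[length(bpRows) + 1L]] <- data.frame(
        transcript_id = txid, intron_index = i, offset = spec$bp1)
      if (!is.na(spec$bp2))
        bpRows[[length(bpRows) + 1L]] <- data.frame(
          transcript_id = txid, intron_index = i, offset = spec$bp2)
    }
    genes[[g]] <- list(txid = txid, symbol = sym, chrom = chrom, strand = strand,
                       exLens = exLens, ivLens = ivLens, utr5 = utr5,
                       cdsLen = cdsLen, exStartT = exStartT, exEndT = exEndT,
                       ivStartT = ivStartT, ivEndT = ivEndT,
                       geneStart = geneStart, geneEnd = geneEnd, Lc = Lc)
  }
  genome <- Biostrings::DNAStringSet(genomeSeqs)
  names(genome) <- paste0("chr", seq_len(spec$nGenes))
  structure(list(genome = genome, gtfLines = gtf,
                 bp = do.call(rbind, bpRows),
                 canonical = vapply(genes, `[[`, character(1), "txid"),
                 genes = genes, spec = spec),
            class = "AgFixture")
}

# one intron on the transcribed strand: GT donor, planted branchpoint(s),
# pyrimidine-rich AG-free zone 1, YAG acceptor end
makeIntron <- function(L, bp1, bp2, pY, suppress, bases) {
  ch <- sample(bases, L, replace = TRUE)
  ch[1:2] <- c("G", "T")
  at <- function(a) L + a + 1L                  # anchored -> index
  ch[at(bp1)] <- "A"
  if (!is.na(bp2)) ch[at(bp2)] <- "A"
  z1 <- (bp1 + 1L):(-4L)
  ch[at(z1)] <- ifelse(stats::runif(length(z1)) < pY,
                       sample(c("C", "T"), length(z1), replace = TRUE),
                       sample(c("A", "G"), length(z1), replace = TRUE))
  ch[at(-3L)] <- sample(c("C", "T"), 1L)
  ch[at(-2L)] <- "A"
  ch[at(-1L)] <- "G"
  if (suppress) {
    for (a in z1) {                             # previous base may be the BP 'A'
      if (ch[at(a)] == "G" && ch[at(a) - 1L] == "A") ch[at(a)] <- "C"
    }
  }
  ch
}

#' Write fixture files (FASTA, GTF, branchpoint TSV, canonical list)
#'
#' @param fix an `AgFixture`.
#' @param dir output directory (created if needed).
#' @return named character vector of paths.
#' @export
writeFixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             bp = file.path(dir, "branchpoints.tsv"),
             canonical = file.path(dir, "canonical.txt"))
  Biostrings::writeXStringSet(fix$genome, paths[["genome"]])
  writeLines(fix$gtfLines, paths[["gtf"]])
  utils::write.table(fix$bp, paths[["bp"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(fix$canonical, paths[["canonical"]])
  paths
}

#' Build a SpliceDb directly from an in-memory fixture
#'
#' Constructs the transcript models from the generator's structural metadata
#' (equivalent to writing the GTF and re-loading it, but without the
#' round-trip), then assembles the database.
#'
#' @param fix an `AgFixture`.
#' @return a [SpliceDb-class].
#' @export
fixtureDb <- function(fix) {
  txs <- list()
  for (gm in fix$genes) {
    mapT2G <- fixtureMapT2G(gm)
    exG <- t(vapply(seq_along(gm$exLens), function(i)
      sort(c(mapT2G(gm$exStartT[i]), mapT2G(gm$exEndT[i]))), integer(2)))
    ord <- order(exG[, 1L], decreasing = (gm$strand == "-"))
    cdsStartT <- fixtureS2T(gm, gm$utr5 + 1L)
    cdsEndT <- fixtureS2T(gm, gm$utr5 + gm$cdsLen)
    txs[[gm$txid]] <- methods::new("TranscriptModel",
      transcriptId = gm$txid, geneSymbol = gm$symbol, chrom = gm$chrom,
      strand = gm$strand,
      exons = IRanges::IRanges(exG[ord, 1L], exG[ord, 2L]),
      cdsStart = mapT2G(cdsStartT), cdsEnd = mapT2G(cdsEndT),
      isCanonical = TRUE)
  }
  buildSpliceDb(fix$genome, txs, fix$bp)
}

fixtureMapT2G <- function(gm) {
  function(t) if (gm$strand == "+") gm$geneStart + t - 1L
              else gm$Lc - (gm$geneStart + t - 1L) + 1L
}

fixtureS2T <- function(gm, s) {
  exCum <- cumsum(gm$exLens)
  i <- findInterval(s, c(0L, exCum) + 1L)
  gm$exStartT[i] + (s - (if (i == 1L) 0L else exCum[i - 1L])) - 1L
}

# transcribed-strand base accessors on the fixture genome, intron-anchored
fixtureGetBase <- function(fix, gi, ivs, a) {
  gm <- fix$genes[[gi]]
  t <- gm$ivEndT[ivs] + a + 1L
  g <- fixtureMapT2G(gm)(t)
  b <- substr(as.character(fix$genome[[gm$chrom]]), g, g)
  if (gm$strand == "-") chartr("ACGT", "TGCA", b) else b
}

fixtureSetBase <- function(fix, gi, ivs, a, base) {
  gm <- fix$genes[[gi]]
  t <- gm$ivEndT[ivs] + a + 1L
  g <- fixtureMapT2G(gm)(t)
  b <- if (gm$strand == "-") chartr("ACGT", "TGCA", base) else base
  x <- fix$genome[[gm$chrom]]
  Biostrings::subseq(x, g, g) <- Biostrings::DNAString(b)
  fix$genome[[gm$chrom]] <- x
  fix
}

fixtureAnchored2G <- function(fix, gi, ivs, a) {
  gm <- fix$genes[[gi]]
  fixtureMapT2G(gm)(gm$ivEndT[ivs] + a + 1L)
}

#' Default planted-variant roster
#'
#' One entry per AG-gain mechanism class plus negative controls (a non-AG
#' SNV, a branchpoint variant, a canonical-acceptor variant, an AG-gain in
#' zone 3, and an AG-preserving deletion); a zone-2 entry is included when
#' the fixture has second branchpoints.
#'
#' @param twoBp include a zone-2 entry.
#' @return roster data.frame.
#' @export
defaultRoster <- function(twoBp = FALSE) {
  r <- data.frame(
    label = c("snvA", "snvG", "delj", "insAG", "insj",
              "neg_snv", "neg_bp", "neg_acc", "neg_zone3", "neg_del_preserve"),
    mechanism = c("snv-new-A", "snv-new-G", "del-junction", "ins-contains-AG",
                  "ins-junction", "neg-snv", "neg-bp", "neg-acc", "neg-zone3",
                  "neg-del-preserve"),
    zone = "ZONE 1",
    bp_dist = c(10L, 12L, 10L, 14L, 9L, 10L, NA, NA, NA, 3L),
    yag = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    yagBase = "C", forceTail = FALSE, stringsAsFactors = FALSE)
  if (twoBp)
    r <- rbind(r, data.frame(label = "z2snvA", mechanism = "snv-new-A",
                             zone = "ZONE 2", bp_dist = 2L, yag = FALSE,
                             yagBase = "C", forceTail = FALSE))
  r
}

#' Roster reproducing the published worked-variant geometries
#'
#' Four SNVs with the printed branchpoint distances (16, 5, 21 and 6 nt,
#' with the 21-nt entry creating a TAG) plus the SPPL2A-like geometry
#' (bpDist 18, accDist 6, YAG, retained tail TTTTAG giving an in-frame
#' Phe-stop insertion), all with BP = -26.
#'
#' @return roster data.frame.
#' @export
paperRoster <- function() {
  data.frame(
    label = c("VAR1", "VAR2", "VAR3", "VAR4", "SPPL2A"),
    mechanism = c("snv-new-G", "snv-new-A", "snv-new-A", "snv-new-A", "snv-new-G"),
    zone = "ZONE 1",
    bp_dist = c(16L, 5L, 21L, 6L, 18L),
    yag = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    yagBase = c("C", "C", "T", "C", "C"),
    forceTail = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Plant a variant roster into a fixture
#'
#' Adjusts reference bases as needed to host each mechanism (without
#' breaking the zone-1 AG-free invariant except for the deliberate
#' AG-preserving-deletion control), back-checks every plant against the
#' resulting sequences, and emits plus-strand VCF records plus a truth
#' table of the expected annotations.
#'
#' @param fix an `AgFixture`.
#' @param roster roster data.frame (see [defaultRoster()]).
#' @return list: `fix` (genome updated with host adjustments), `vcfLines`,
#'   `truth` data.frame.
#' @export
simulateVariants <- function(fix, roster = defaultRoster()) {
  nG <- length(fix$genes)
  slots <- do.call(rbind, lapply(seq_len(nG), function(g)
    data.frame(gi = g, ivs = seq_along(fix$genes[[g]]$ivLens))))
  if (nrow(roster) > nrow(slots))
    stop("roster larger than the number of available introns")
  bp1 <- fix$spec$bp1; bp2 <- fix$spec$bp2
  vcf <- list(); truth <- list()

  for (e in seq_len(nrow(roster))) {
    r <- roster[e, ]
    gi <- slots$gi[e]; ivs <- slots$ivs[e]
    gm <- fix$genes[[gi]]
    anchor <- if (identical(r$zone, "ZONE 2")) bp2 else bp1
    if (identical(r$zone, "ZONE 2") && is.na(bp2))
      stop(sprintf("roster entry %s: zone-2 plant needs a two-BP fixture", r$label))
    d <- r$bp_dist
    setB <- function(a, b) fix <<- fixtureSetBase(fix, gi, ivs, a, b)
    getB <- function(a) fixtureGetBase(fix, gi, ivs, a)
    setYagBase <- function(a) {         # base 5' of the created A
      if (a - 1L > anchor) setB(a - 1L, if (r$yag) r$yagBase else "A")
      else if (r$yag) stop(sprintf("roster entry %s: YAG unplantable at bp_dist 1", r$label))
    }
    ivsTag <- sprintf("%s_IVS%d", gm$txid, ivs)
    edit <- NULL  # list(type, ...anchored transcribed-strand edit)

    if (r$mechanism == "snv-new-A") {
      a <- anchor + d
      setB(a, "T"); setB(a + 1L, "G"); setYagBase(a)
      edit <- list(type = "snv", at = a, refT = "T", altT = "A")
      expectCall(truth) <- list(r = r, ivsTag = ivsTag, a = a, g = a + 1L,
                                bp1 = bp1, anchor = anchor)
    } else if (r$mechanism == "snv-new-G") {
      a <- anchor + d; g2 <- a + 1L
      setB(a, "A"); setB(g2, "A")
      if (getB(g2 + 1L) == "G") setB(g2 + 1L, "T")
      setYagBase(a)
      if (r$forceTail) for (k in -6:-3) setB(k, "T")
      edit <- list(type = "snv", at = g2, refT = "A", altT = "G")
      expectCall(truth) <- list(r = r, ivsTag = ivsTag, a = a, g = g2,
                                bp1 = bp1, anchor = anchor)
    } else if (r$mechanism == "del-junction") {
      p <- anchor + d
      setB(p, "A"); setB(p + 1L, "C"); setB(p + 2L, "T"); setB(p + 3L, "G")
      setYagBase(p)
      edit <- list(type = "del", from = p + 1L, to = p + 2L)
      expectCall(truth) <- list(r = r, ivsTag = ivsTag, a = p + 2L, g = p + 3L,
                                bp1 = bp1 + 2L, anchor = anchor + 2L)
    } else if (r$mechanism == "ins-contains-AG") {
      q <- anchor + d - 1L
      setB(q, if (r$yag) r$yagBase else "A")
      if (getB(q + 1L) == "G") setB(q + 1L, "T")
      edit <- list(type = "ins", after = q, seqT = "AG")
      expectCall(truth) <- list(r = r, ivsTag = ivsTag, a = q - 1L, g = q,
                                bp1 = bp1 - 2L, anchor = anchor - 2L)
    } else if (r$mechanism == "ins-junction") {
      q <- anchor + d
      setB(q, "A")
      if (getB(q + 1L) == "G") setB(q + 1L, "T")
      setYagBase(q)
      edit <- list(type = "ins", after = q, seqT = "G")
      expectCall(truth) <- list(r = r, ivsTag = ivsTag, a = q - 1L, g = q,
                                bp1 = bp1 - 1L, anchor = anchor - 1L)
    } else if (r$mechanism == "neg-snv") {
      a <- anchor + d
      if (getB(a) == "C") setB(a, "T")
      edit <- list(type = "snv", at = a, refT = getB(a), altT = "C")
      expectNone(truth) <- list(r = r, ivsTag = ivsTag, reason = NA_character_)
    } else if (r$mechanism == "neg-bp") {
      edit <- list(type = "snv", at = bp1, refT = "A", altT = "C")
      expectNone(truth) <- list(r = r, ivsTag = ivsTag,
                                reason = "BP-variant (BPHunter scope)")
    } else if (r$mechanism == "neg-acc") {
      edit <- list(type = "snv", at = -2L, refT = "A", altT = "T")
      expectNone(truth) <- list(r = r, ivsTag = ivsTag,
                                reason = "canonical-ACC variant")
    } else if (r$mechanism == "neg-zone3") {
      z <- (if (is.na(bp2)) bp1 else bp2) - 10L
      setB(z, "T"); setB(z + 1L, "G")
      edit <- list(type = "snv", at = z, refT = "T", altT = "A")
      expectNone(truth) <- list(r = r, ivsTag = ivsTag, reason = NA_character_)
    } else if (r$mechanism == "neg-del-preserve") {
      p <- anchor + d
      setB(p, "A"); setB(p + 1L, "A"); setB(p + 2L, "G")
      if (getB(p + 3L) == "G") setB(p + 3L, "T")   # keep the REF AG unique
      edit <- list(type = "del", from = p + 1L, to = p + 1L)
      expectNone(truth) <- list(r = r, ivsTag = ivsTag, reason = NA_character_)
    } else stop(sprintf("unknown roster mechanism '%s'", r$mechanism))

    vcf[[length(vcf) + 1L]] <- fixtureEditToVcf(fix, gi, ivs, r$label, edit)
    truth[[length(truth)]]$chrom <- gm$chrom
    truth[[length(truth)]]$vcf <- vcf[[length(vcf)]]
    backCheckPlant(fix, gi, ivs, truth[[length(truth)]], edit, r)
  }

  vcfDf <- if (length(vcf)) do.call(rbind, c(vcf, list(make.row.names = FALSE)))
           else NULL
  truthDf <- if (length(truth))
    do.call(rbind, c(lapply(truth, truthRow), list(make.row.names = FALSE)))
  else NULL
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(fix$genome),
                      Biostrings::width(fix$genome)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (is.null(vcfDf) || !nrow(vcfDf)) character() else {
    ord <- order(vcfDf$CHROM, vcfDf$POS)
    vcfDf <- vcfDf[ord, , drop = FALSE]
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", vcfDf$CHROM, vcfDf$POS, vcfDf$ID,
            vcfDf$REF, vcfDf$ALT)
  }
  list(fix = fix, vcfLines = c(header, body),
       truth = if (is.null(truthDf)) emptyTruth() else truthDf)
}

`expectCall<-` <- function(x, value) {
  r <- value$r
  zone <- r$zone
  hr <- zone == "ZONE 1" && (value$a - value$bp1) >= 8L
  accDist <- -value$g - 1L
  c(x, list(list(label = r$label, ivsTag = value$ivsTag, expect = TRUE,
    zone = zone, mechanism = r$mechanism, a_pos = value$a, g_pos = value$g,
    yag = r$yag, bp_dist = value$a - value$anchor, acc_dist = accDist,
    high_risk = hr,
    score = as.integer(1L + (zone == "ZONE 1") + hr + r$yag + (accDist <= 17L)),
    reason = NA_character_)))
}

`expectNone<-` <- function(x, value) {
  c(x, list(list(label = value$r$label, ivsTag = value$ivsTag, expect = FALSE,
    zone = NA_character_, mechanism = value$r$mechanism, a_pos = NA_integer_,
    g_pos = NA_integer_, yag = NA, bp_dist = NA_integer_,
    acc_dist = NA_integer_, high_risk = NA, score = NA_integer_,
    reason = value$reason)))
}

truthRow <- function(t) {
  data.frame(label = t$label, chrom = t$chrom, pos = t$vcf$POS, ref = t$vcf$REF,
             alt = t$vcf$ALT, transcript_ivs = t$ivsTag, expect_call = t$expect,
             zone = t$zone, mechanism = t$mechanism, a_pos = t$a_pos,
             g_pos = t$g_pos, yag = t$yag, bp_dist = t$bp_dist,
             acc_dist = t$acc_dist, high_risk = t$high_risk, score = t$score,
             reject_reason = t$reason, stringsAsFactors = FALSE)
}

emptyTruth <- function() {
  data.frame(label = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), transcript_ivs = character(),
             expect_call = logical(), zone = character(), mechanism = character(),
             a_pos = integer(), g_pos = integer(), yag = logical(),
             bp_dist = integer(), acc_dist = integer(), high_risk = logical(),
             score = integer(), reject_reason = character())
}

# anchored transcribed-strand edit -> plus-strand VCF record
fixtureEditToVcf <- function(fix, gi, ivs, label, edit) {
  gm <- fix$genes[[gi]]
  gOf <- function(a) fixtureAnchored2G(fix, gi, ivs, a)
  chromSeq <- as.character(fix$genome[[gm$chrom]])
  baseAt <- function(g) substr(chromSeq, g, g)
  revc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (edit$type == "snv") {
    g <- gOf(edit$at)
    ref <- if (gm$strand == "-") chartr("ACGT", "TGCA", edit$refT) else edit$refT
    alt <- if (gm$strand == "-") chartr("ACGT", "TGCA", edit$altT) else edit$altT
    return(data.frame(CHROM = gm$chrom, POS = g, ID = label, REF = ref,
                      ALT = alt, stringsAsFactors = FALSE))
  }
  if (edit$type == "del") {
    gs <- sort(c(gOf(edit$from), gOf(edit$to)))
    pos <- gs[1L] - 1L
    ref <- substr(chromSeq, pos, gs[2L])
    return(data.frame(CHROM = gm$chrom, POS = pos, ID = label, REF = ref,
                      ALT = baseAt(pos), stringsAsFactors = FALSE))
  }
  # insertion of seqT between anchored `after` and `after`+1
  gA <- gOf(edit$after); gB <- gOf(edit$after + 1L)
  pos <- min(gA, gB)
  ins <- if (gm$strand == "-") revc(edit$seqT) else edit$seqT
  data.frame(CHROM = gm$chrom, POS = pos, ID = label, REF = baseAt(pos),
             ALT = paste0(baseAt(pos), ins), stringsAsFactors = FALSE)
}

# verify a plant against the actual sequences (independent of the scanner):
# rebuild the local REF and ALT transcribed-strand context and confirm the
# expected AG is present in ALT at the expected position and absent in REF
backCheckPlant <- function(fix, gi, ivs, truthEntry, edit, r) {
  if (!truthEntry$expect) return(invisible(TRUE))
  win <- -40:-1
  refCh <- vapply(win, function(a) fixtureGetBase(fix, gi, ivs, a), character(1))
  altCh <- refCh
  at <- function(a) a + 41L
  if (edit$type == "snv") {
    altCh[at(edit$at)] <- edit$altT
  } else if (edit$type == "del") {
    altCh <- altCh[-(at(edit$from):at(edit$to))]
  } else {
    altCh <- append(altCh, strsplit(edit$seqT, "")[[1L]], after = at(edit$after))
  }
  altAnch <- seq_along(altCh) - length(altCh) - 1L
  iA <- which(altAnch == truthEntry$a_pos)
  ok <- length(iA) == 1L && altCh[iA] == "A" && altCh[iA + 1L] == "G"
  if (ok && edit$type == "snv") {
    ok <- !(refCh[at(truthEntry$a_pos)] == "A" &&
            refCh[at(truthEntry$g_pos)] == "G")
  }
  if (!ok)
    stop(sprintf("roster entry %s unplantable in the fixture", r$label))
  invisible(TRUE)
}

#' Write VCF lines to a file
#' @param vcfLines character vector from [simulateVariants()].
#' @param path output path.
#' @export
writeVcfLines <- function(vcfLines, path) writeLines(vcfLines, path)

#' Reverse-complement a fixture
#'
#' Flips every contig to its reverse complement and toggles every gene's
#' strand, leaving all transcript-space structure (exon/intron lengths,
#' branchpoint offsets, zone arithmetic) unchanged. Scanning the flipped
#' fixture must reproduce the original transcript-space annotations exactly;
#' this is the package's strand-symmetry check.
#'
#' @param fix an `AgFixture`.
#' @return the flipped fixture (GTF lines are dropped; use [fixtureDb()]).
#' @export
revCompFixture <- function(fix) {
  fix$genome <- Biostrings::reverseComplement(fix$genome)
  fix$genes <- lapply(fix$genes, function(gm) {
    gm$strand <- if (gm$strand == "+") "-" else "+"
    gm
  })
  fix$gtfLines <- NULL
  fix
}
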