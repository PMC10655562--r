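# Shared fixtures and independent oracles for the test suite.

# parse generator VCF lines into the 5-column data.frame scanVariants accepts
vcfLinesToDf <- function(vcfLines) {
  body <- grep("^#", vcfLines, invert = TRUE, value = TRUE)
  if (!length(body))
    return(data.frame(CHROM = character(), POS = integer(), ID = character(),
                      REF = character(), ALT = character()))
  df <- read.table(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)[, 1:5]
  names(df) <- c("CHROM", "POS", "ID", "REF", "ALT")
  df
}

# standard small planted fixture used across files
plantedFixture <- function(seed = 42, roster = defaultRoster(), nGenes = 5L, ...) {
  fix <- simulateReference(fixtureSpec(nGenes = nGenes, seed = seed, ...))
  vs <- simulateVariants(fix, roster)
  list(vs = vs, db = fixtureDb(vs$fix))
}

# fixture with controlled exon phases hosting the published variant geometries
paperGeometryFixture <- function(seed = 7) {
  gd <- list(strand = "+", exonLens = c(60L, 63L, 60L),
             intronLens = c(120L, 120L), utr5 = 9L)
  gds <- list(gd, within(gd, strand <- "-"), gd)
  fix <- simulateReference(fixtureSpec(nGenes = 3, seed = seed, genes = gds))
  vs <- simulateVariants(fix, paperRoster())
  list(vs = vs, db = fixtureDb(vs$fix))
}

# ---- independent AG-gain oracle ---------------------------------------------
# Rebuilds the ENTIRE mutant intron, lists AG loci in REF and ALT, and calls
# an ALT AG iff it overlaps the edit and its locus is not in the REF AG set.
# Shares no code with agscan::detectAgGain.

oracleDetect <- function(db, txid, ivs, pos, ref, alt) {
  gr <- introns(db)
  m <- S4Vectors::mcols(gr)
  i <- which(m$transcript_id == txid & m$intron_index == ivs)[1]
  istart <- GenomicRanges::start(gr)[i]; iend <- GenomicRanges::end(gr)[i]
  strand <- as.character(GenomicRanges::strand(gr))[i]
  refFull <- strsplit(m$seq[i], "")[[1]]
  L <- length(refFull)
  zt <- zoneTable(db)
  z <- zt[zt$transcript_id == txid & zt$intron_index == ivs, ][1, ]
  if (is.na(z$bp1)) return(list(calls = oracleEmpty(), reason = "no-BP"))

  # own trimming
  ref <- toupper(ref); alt <- toupper(alt)
  p <- 0
  while (p < min(nchar(ref), nchar(alt)) &&
         substr(ref, p + 1, p + 1) == substr(alt, p + 1, p + 1)) p <- p + 1
  s <- 0
  while (s < min(nchar(ref), nchar(alt)) - p &&
         substr(ref, nchar(ref) - s, nchar(ref) - s) ==
         substr(alt, nchar(alt) - s, nchar(alt) - s)) s <- s + 1
  rc <- substr(ref, p + 1, nchar(ref) - s)
  ac <- substr(alt, p + 1, nchar(alt) - s)
  gs <- pos + p; ge <- pos + nchar(ref) - s - 1

  anch <- function(g) if (strand == "+") g - iend - 1L else istart - g - 1L
  revc <- function(x) if (nzchar(x))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))) else x

  bps <- c(z$bp1, z$bp2); bps <- bps[!is.na(bps)]
  bpg <- vapply(bps, function(o)
    if (strand == "+") iend + o + 1L else istart - o - 1L, numeric(1))
  isIns <- !nzchar(rc)
  if (!isIns && any(bpg >= gs & bpg <= ge))
    return(list(calls = oracleEmpty(), reason = "BP-variant (BPHunter scope)"))
  t3g <- vapply(c(-1, -2, -3), function(o)
    if (strand == "+") iend + o + 1L else istart - o - 1L, numeric(1))
  if (!isIns && any(t3g >= gs & t3g <= ge))
    return(list(calls = oracleEmpty(), reason = "canonical-ACC variant"))
  if (isIns && max(anch(gs - 1L), anch(gs)) >= -3 &&
      min(anch(gs - 1L), anch(gs)) >= -3)
    return(list(calls = oracleEmpty(), reason = "canonical-ACC variant"))
  if (!isIns && (gs < istart || ge > iend))
    return(list(calls = oracleEmpty(), reason = "not-intronic"))

  # transcribed-strand edit on the full intron
  acT <- if (strand == "-") revc(ac) else ac
  if (isIns) {
    q <- min(anch(gs - 1L), anch(gs))
    iFrom <- L + q + 2L; iTo <- L + q + 1L   # empty interval after index L+q+1
  } else {
    b <- sort(c(anch(gs), anch(ge)))
    iFrom <- L + b[1] + 1L; iTo <- L + b[2] + 1L
  }
  edited <- rep(FALSE, L)
  altFull <- refFull; origin <- seq_len(L) - L - 1L
  if (isIns) {
    ins <- strsplit(acT, "")[[1]]
    altFull <- append(refFull, ins, after = iTo)
    origin <- append(origin, rep(NA, length(ins)), after = iTo)
    editedAlt <- append(edited, rep(TRUE, length(ins)), after = iTo)
  } else if (!nzchar(acT)) {
    altFull <- refFull[-(iFrom:iTo)]
    origin <- origin[-(iFrom:iTo)]
    editedAlt <- edited[-(iFrom:iTo)]
  } else if (nchar(rc) == nchar(acT)) {
    altFull[iFrom:iTo] <- strsplit(acT, "")[[1]]
    editedAlt <- edited; editedAlt[iFrom:iTo] <- altFull[iFrom:iTo] != refFull[iFrom:iTo]
  } else {
    ins <- strsplit(acT, "")[[1]]
    altFull <- c(refFull[seq_len(iFrom - 1)], ins,
                 refFull[seq.int(iTo + 1, L)])
    origin <- c(origin[seq_len(iFrom - 1)], rep(NA, length(ins)),
                seq.int(iTo + 1, L) - L - 1L)
    editedAlt <- is.na(c(origin))[seq_along(altFull)]
  }
  # sanity: observed REF core must match the genome
  if (!isIns) {
    obs <- paste(refFull[iFrom:iTo], collapse = "")
    if (obs != (if (strand == "-") revc(rc) else rc))
      return(list(calls = oracleEmpty(), reason = "ref-mismatch"))
  }
  La <- length(altFull)
  altAnch <- seq_len(La) - La - 1L
  refAG <- which(refFull[-L] == "A" & refFull[-1] == "G") - L - 1L  # anchored A pos
  bp1a <- altAnch[match(z$bp1, origin)]
  bp2a <- if (!is.na(z$bp2)) altAnch[match(z$bp2, origin)] else NA

  calls <- list()
  for (k in seq_len(La - 1)) {
    if (altFull[k] != "A" || altFull[k + 1] != "G") next
    aA <- altAnch[k]; gA <- altAnch[k + 1]
    zone <- if (aA >= bp1a + 1 && gA <= -4) "ZONE 1"
            else if (!is.na(bp2a) && aA >= bp2a + 1 && gA <= bp1a - 1) "ZONE 2"
            else next
    o1 <- origin[k]; o2 <- origin[k + 1]
    touches <- editedAlt[k] || editedAlt[k + 1] || is.na(o1) || is.na(o2) ||
      (!is.na(o1) && !is.na(o2) && o2 > o1 + 1)
    if (!touches) next
    old <- (!is.na(o1) && !editedAlt[k] && (o1 %in% refAG)) ||
           (!is.na(o2) && !editedAlt[k + 1] && ((o2 - 1) %in% refAG))
    if (old) next
    mech <- if (nzchar(rc) && nzchar(ac) && nchar(rc) != nchar(ac)) "complex"
      else if (is.na(o1) && is.na(o2)) "ins-contains-AG"
      else if (is.na(o1) || is.na(o2)) "ins-junction"
      else if (o2 > o1 + 1) "del-junction"
      else if (editedAlt[k] && editedAlt[k + 1]) "complex"
      else if (editedAlt[k]) "snv-new-A" else "snv-new-G"
    yag <- k > 1 && altFull[k - 1] %in% c("C", "T")
    bpd <- aA - (if (zone == "ZONE 1") bp1a else bp2a)
    acd <- -gA - 1
    hr <- zone == "ZONE 1" && bpd >= 8
    calls[[length(calls) + 1]] <- data.frame(zone = zone, a_pos = aA, g_pos = gA,
      mechanism = mech, yag = yag, bp_dist = bpd, acc_dist = acd,
      high_risk = hr,
      score = as.integer(min(5, 1 + (zone == "ZONE 1") + hr + yag + (acd <= 17))),
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else oracleEmpty()
  calls <- calls[!duplicated(calls[, c("a_pos", "g_pos")]), , drop = FALSE]
  list(calls = calls, reason = NA_character_)
}

oracleEmpty <- function() {
  data.frame(zone = character(), a_pos = integer(), g_pos = integer(),
             mechanism = character(), yag = logical(), bp_dist = integer(),
             acc_dist = integer(), high_risk = logical(), score = integer(),
             stringsAsFactors = FALSE)
}

# compare detectAgGain with the oracle for one variant
expectOracleAgreement <- function(db, txid, ivs, pos, ref, alt) {
  got <- detectAgGain(db, txid, ivs, pos, ref, alt)
  want <- oracleDetect(db, txid, ivs, pos, ref, alt)
  cols <- c("zone", "a_pos", "g_pos", "mechanism", "yag", "bp_dist",
            "acc_dist", "high_risk", "score")
  norm <- function(d) {
    d <- d[order(d$a_pos), cols, drop = FALSE]
    for (cc in c("a_pos", "g_pos", "bp_dist", "acc_dist", "score"))
      d[[cc]] <- as.integer(d[[cc]])
    rownames(d) <- NULL
    d
  }
  g <- norm(got); w <- norm(want$calls)
  rGot <- attr(got, "reason"); if (is.null(rGot)) rGot <- NA_character_
  ok <- identical(g, w) &&
    (identical(is.na(rGot), is.na(want$reason))) &&
    (is.na(want$reason) || identical(rGot, want$reason))
  if (!ok) {
    info <- sprintf("%s_IVS%d %d %s>%s", txid, ivs, pos, ref, alt)
    testthat::fail(paste("oracle mismatch at", info,
                         "\n got:", paste(capture.output(print(g)), collapse = "\n"),
                         "\n want:", paste(capture.output(print(w)), collapse = "\n"),
                         "\n reasons:", attr(got, "reason"), "vs", want$reason))
  }
  invisible(ok)
}

# random intronic variants for the oracle-equivalence property
randomVariantRoster <- function(db, n, seed) {
  set.seed(seed)
  gr <- introns(db)
  m <- S4Vectors::mcols(gr)
  zt <- zoneTable(db)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n)
  for (k in seq_len(n)) {
    i <- sample(length(gr), 1)
    istart <- GenomicRanges::start(gr)[i]; iend <- GenomicRanges::end(gr)[i]
    strand <- as.character(GenomicRanges::strand(gr))[i]
    L <- iend - istart + 1
    # anchored position in/near the zones, including BP and terminal bases
    a <- sample(seq.int(max(-L, -45L), -1L), 1)
    g <- if (strand == "+") iend + a + 1 else istart - a - 1
    type <- sample(c("snv", "del", "ins", "mnv"), 1,
                   prob = c(0.5, 0.2, 0.2, 0.1))
    chromSeq <- db@genome[[as.character(GenomicRanges::seqnames(gr))[i]]]
    baseAt <- function(p) as.character(Biostrings::subseq(chromSeq, p, p))
    if (type == "snv") {
      ref <- baseAt(g); alt <- sample(setdiff(bases, ref), 1)
      pos <- g
    } else if (type == "del") {
      w <- sample(1:3, 1)
      pos <- max(istart, g - w)
      ref <- paste(vapply(pos:(pos + w), baseAt, character(1)), collapse = "")
      alt <- baseAt(pos)
    } else if (type == "ins") {
      w <- sample(1:3, 1)
      pos <- g
      ref <- baseAt(g)
      alt <- paste0(ref, paste(sample(bases, w, replace = TRUE), collapse = ""))
    } else {
      w <- sample(2:3, 1)
      pos <- max(istart, g - w + 1)
      ref <- paste(vapply(pos:(pos + w - 1), baseAt, character(1)), collapse = "")
      alt <- paste(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
      if (alt == ref) alt <- paste0(alt, "A")
    }
    out[[k]] <- data.frame(txid = m$transcript_id[i], ivs = m$intron_index[i],
                           pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- HGVS round-trip applier -------------------------------------------------
# Applies an emitted p. description to the WT protein. For frameshifts the
# notation does not encode the substituted tail, so consistency (prefix, first
# changed residue, stop position) is verified instead of full reconstruction.
AA1 <- setNames(names(agscan:::AA3), agscan:::AA3)

hgvsRoundTrip <- function(wt, mut, hgvs) {
  aa1 <- function(x) {
    if (x == "*") return("*")
    paste(AA1[regmatches(x, gregexpr("([A-Z][a-z]{2}|\\*)", x))[[1]]], collapse = "")
  }
  if (hgvs == "p.(=)") return(identical(wt, mut))
  if (hgvs == "p.0?") return(identical(mut, ""))
  mFs <- regmatches(hgvs, regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})fs\\*(\\d+)$", hgvs))[[1]]
  if (length(mFs)) {
    pos <- as.integer(mFs[3]); N <- as.integer(mFs[5])
    return(substr(mut, 1, pos - 1) == substr(wt, 1, pos - 1) &&
           substr(wt, pos, pos) == AA1[mFs[2]] &&
           substr(mut, pos, pos) == AA1[mFs[4]] &&
           nchar(mut) == pos + N - 2)
  }
  mNon <- regmatches(hgvs, regexec("^p\\.([A-Z][a-z]{2})(\\d+)\\*$", hgvs))[[1]]
  if (length(mNon)) {
    pos <- as.integer(mNon[3])
    return(identical(mut, substr(wt, 1, pos - 1)) &&
           substr(wt, pos, pos) == AA1[mNon[2]])
  }
  mInsStop <- regmatches(hgvs, regexec(
    "^p\\.([A-Z][a-z]{2})(\\d+)_([A-Z][a-z]{2})(\\d+)ins((?:[A-Z][a-z]{2})+)\\*$", hgvs))[[1]]
  if (length(mInsStop)) {
    pos <- as.integer(mInsStop[3])
    return(identical(mut, paste0(substr(wt, 1, pos), aa1(mInsStop[6]))))
  }
  mIns <- regmatches(hgvs, regexec(
    "^p\\.([A-Z][a-z]{2})(\\d+)_([A-Z][a-z]{2})(\\d+)ins((?:[A-Z][a-z]{2})+)$", hgvs))[[1]]
  if (length(mIns)) {
    pos <- as.integer(mIns[3])
    return(identical(mut, paste0(substr(wt, 1, pos), aa1(mIns[6]),
                                 substr(wt, pos + 1, nchar(wt)))))
  }
  mDel <- regmatches(hgvs, regexec(
    "^p\\.([A-Z][a-z]{2})(\\d+)(?:_([A-Z][a-z]{2})(\\d+))?del$", hgvs))[[1]]
  if (length(mDel)) {
    from <- as.integer(mDel[3])
    to <- if (nzchar(mDel[5])) as.integer(mDel[5]) else from
    return(identical(mut, paste0(substr(wt, 1, from - 1),
                                 substr(wt, to + 1, nchar(wt)))))
  }
  mDelIns <- regmatches(hgvs, regexec(
    "^p\\.([A-Z][a-z]{2})(\\d+)(?:_([A-Z][a-z]{2})(\\d+))?delins((?:[A-Z][a-z]{2}|\\*)+)$", hgvs))[[1]]
  if (length(mDelIns)) {
    from <- as.integer(mDelIns[3])
    to <- if (nzchar(mDelIns[5])) as.integer(mDelIns[5]) else from
    return(identical(mut, paste0(substr(wt, 1, from - 1), aa1(mDelIns[6]),
                                 substr(wt, to + 1, nchar(wt)))))
  }
  mSub <- regmatches(hgvs, regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", hgvs))[[1]]
  if (length(mSub)) {
    pos <- as.integer(mSub[3])
    return(identical(mut, paste0(substr(wt, 1, pos - 1), AA1[mSub[4]],
                                 substr(wt, pos + 1, nchar(wt)))))
  }
  FALSE
}
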