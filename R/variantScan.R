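#' @include AllClasses.R
NULL

#' Normalize VCF records to minimal per-ALT variants
#'
#' Splits multi-allelic records, drops symbolic/breakend alleles with a
#' warning, rejects REF == ALT, and trims shared prefix/suffix down to the
#' minimal representation (a single anchor base is kept in the VCF-style
#' `ref`/`alt` fields for indels; `var_type` carries the indel length).
#'
#' @param df data.frame with columns CHROM, POS, ID, REF, ALT (ALT may be
#'   comma-separated).
#' @return data.frame: chrom, pos, id, ref, alt, var_type, line_id.
#' @export
normalizeVariants <- function(df) {
  names(df)[1:5] <- c("CHROM", "POS", "ID", "REF", "ALT")
  out <- list()
  for (i in seq_len(nrow(df))) {
    alts <- strsplit(as.character(df$ALT[i]), ",", fixed = TRUE)[[1L]]
    ref0 <- toupper(as.character(df$REF[i]))
    for (alt0 in toupper(alts)) {
      if (grepl("[][<>*.]", alt0) || !nzchar(alt0)) {
        warning(sprintf("record %d: symbolic/breakend ALT '%s' skipped", i, alt0))
        next
      }
      if (identical(ref0, alt0)) {
        warning(sprintf("record %d: REF equals ALT; rejected", i))
        next
      }
      tr <- trimAllele(as.integer(df$POS[i]), ref0, alt0)
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(df$CHROM[i]), pos = tr$pos, id = as.character(df$ID[i]),
        ref = tr$ref, alt = tr$alt, var_type = tr$var_type, line_id = i,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(),
                      var_type = character(), line_id = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# trim to minimal representation; keep one anchor base for indels (VCF style)
trimAllele <- function(pos, ref, alt) {
  co <- coreEdit(pos, ref, alt)
  nr <- nchar(co$refCore); na <- nchar(co$altCore)
  if (nr == 0L) {           # insertion: anchor base on the left
    apos <- co$gs - 1L
    anchor <- substr(ref, apos - pos + 1L, apos - pos + 1L)
    if (!nzchar(anchor)) anchor <- substr(ref, 1L, 1L)  # leading-edge edge case
    list(pos = apos, ref = anchor, alt = paste0(anchor, co$altCore),
         var_type = sprintf("%d nt-insertion", na))
  } else if (na == 0L) {    # deletion
    apos <- co$gs - 1L
    if (apos >= pos) {
      anchor <- substr(ref, apos - pos + 1L, apos - pos + 1L)
      list(pos = apos, ref = paste0(anchor, co$refCore), alt = anchor,
           var_type = sprintf("%d nt-deletion", nr))
    } else {
      list(pos = co$gs, ref = co$refCore, alt = "",
           var_type = sprintf("%d nt-deletion", nr))
    }
  } else if (nr == 1L && na == 1L) {
    list(pos = co$gs, ref = co$refCore, alt = co$altCore, var_type = "snv")
  } else {
    list(pos = co$gs, ref = co$refCore, alt = co$altCore, var_type = "complex")
  }
}

# fully trimmed edit: refCore replaced by altCore at genomic [gs, ge]
# (empty refCore: insertion between gs-1 and gs)
coreEdit <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  p <- 0L
  while (p < min(nr, na) &&
         substr(ref, p + 1L, p + 1L) == substr(alt, p + 1L, p + 1L)) p <- p + 1L
  s <- 0L
  while (s < min(nr, na) - p &&
         substr(ref, nr - s, nr - s) == substr(alt, na - s, na - s)) s <- s + 1L
  list(gs = pos + p, ge = pos + nr - s - 1L,
       refCore = substr(ref, p + 1L, nr - s),
       altCore = substr(alt, p + 1L, na - s))
}

#' Distances of a created AG to branchpoint and acceptor
#'
#' `bpDist` is the offset of the created A downstream of the anchoring
#' branchpoint; `accDist` the number of intronic nucleotides 3' of the
#' created G, i.e. the retained-intron length if the new acceptor is used.
#'
#' @param aPos,gPos 3'-anchored positions of the created AG (ALT frame).
#' @param bpAnchor 3'-anchored branchpoint position (ALT frame).
#' @return list(bpDist, accDist).
#' @export
computeDistances <- function(aPos, gPos, bpAnchor) {
  if (aPos <= bpAnchor || gPos > -4L)
    stop("internal error: created AG outside [BP+1, ACC-4]")
  list(bpDist = aPos - bpAnchor, accDist = -gPos - 1L)
}

#' High-risk classification of an AG-gain call
#'
#' TRUE iff the call lies in zone 1 with the created A at least 8 nt
#' downstream of the first branchpoint (the [BP+8, ACC-4] region in which
#' natural AG/YAG are extremely depleted).
#'
#' @param zone "ZONE 1" or "ZONE 2".
#' @param bpDist distance from the created A to the anchoring branchpoint.
#' @return logical.
#' @export
classifyRisk <- function(zone, bpDist) {
  zone == "ZONE 1" && bpDist >= 8L
}

#' Priority score of an AG-gain call
#'
#' Additive 1-5 scheme: 1 point for any AG-gain in zone 1/2, plus one point
#' each for zone-1 location, the high-risk tag, YAG creation, and acceptor
#' proximity (accDist <= 17, the window containing 95% of published
#' pathogenic calls). Weights are overridable.
#'
#' @param zone "ZONE 1"/"ZONE 2".
#' @param highRisk,yag logicals.
#' @param accDist integer.
#' @param weights named numeric: base, zone1, highrisk, yag, proximal.
#' @param accDistMax proximity cutoff (default 17).
#' @return integer clamped to [1, 5].
#' @export
scoreCall <- function(zone, highRisk, yag, accDist,
                      weights = c(base = 1, zone1 = 1, highrisk = 1,
                                  yag = 1, proximal = 1),
                      accDistMax = 17L) {
  s <- weights[["base"]] +
    weights[["zone1"]] * (zone == "ZONE 1") +
    weights[["highrisk"]] * isTRUE(highRisk) +
    weights[["yag"]] * isTRUE(yag) +
    weights[["proximal"]] * (accDist <= accDistMax)
  as.integer(max(1L, min(5L, s)))
}

#' Detect AG-gain events of one variant in one intron
#'
#' Builds the ALT-allele local sequence on the transcribed strand, enumerates
#' AG dinucleotides whose span includes an edited/inserted base or the
#' deletion junction and whose locus was not an AG in the REF alignment, and
#' annotates each with mechanism class, ALT-frame 3'-anchored coordinates
#' (counted back from the unchanged intron 3' end), distances, YAG context,
#' high-risk tag and score. Variants touching a branchpoint nucleotide or the
#' intron's terminal 3 nt are rejected with a reason code.
#'
#' @param db a [SpliceDb-class].
#' @param transcriptId,intronIndex intron identifier.
#' @param pos,ref,alt plus-strand VCF-style variant (possibly un-trimmed).
#' @return data.frame of calls (0 or more rows) with attribute `reason` set
#'   when the variant was rejected or out of scope.
#' @export
detectAgGain <- function(db, transcriptId, intronIndex, pos, ref, alt) {
  emptyCall <- function(reason) {
    out <- data.frame(zone = character(), a_pos = integer(), g_pos = integer(),
                      mechanism = character(), yag = logical(),
                      bp_dist = integer(), acc_dist = integer(),
                      high_risk = logical(), score = integer(),
                      retained_seq = character())
    attr(out, "reason") <- reason
    out
  }
  m <- S4Vectors::mcols(db@introns)
  ii <- which(m$transcript_id == transcriptId & m$intron_index == intronIndex)
  if (!length(ii)) return(emptyCall("unknown-intron"))
  ii <- ii[1L]
  istart <- GenomicRanges::start(db@introns)[ii]
  iend <- GenomicRanges::end(db@introns)[ii]
  strand <- as.character(GenomicRanges::strand(db@introns))[ii]
  iseq <- m$seq[ii]
  L <- nchar(iseq)

  zt <- db@zoneTable
  z <- zt[zt$transcript_id == transcriptId & zt$intron_index == intronIndex, ]
  if (!nrow(z) || !is.na(z$skipped[1L])) {
    if (nrow(z) && identical(z$skipped[1L], "no-BP")) return(emptyCall("no-BP"))
    if (!nrow(z)) return(emptyCall("no-BP"))
  }
  bp1 <- z$bp1[1L]; bp2 <- z$bp2[1L]
  if (is.na(bp1)) return(emptyCall("no-BP"))

  co <- coreEdit(pos, toupper(ref), toupper(alt))
  isIns <- !nzchar(co$refCore)
  aOf <- function(g) genomicToAnchored(istart, iend, strand, g)

  # rejection: edit overlapping a branchpoint nucleotide
  bpg <- anchoredToGenomic(istart, iend, strand, bp1)
  if (!is.na(bp2)) bpg <- c(bpg, anchoredToGenomic(istart, iend, strand, bp2))
  if (!isIns && any(bpg >= co$gs & bpg <= co$ge))
    return(emptyCall("BP-variant (BPHunter scope)"))
  # rejection: edit overlapping the canonical terminal 3 nt
  t3 <- anchoredToGenomic(istart, iend, strand, c(-1L, -2L, -3L))
  if (!isIns && any(t3 >= co$gs & t3 <= co$ge))
    return(emptyCall("canonical-ACC variant"))
  if (isIns) {
    f <- sort(aOf(c(co$gs - 1L, co$gs)))
    if (f[1L] >= -3L) return(emptyCall("canonical-ACC variant"))
  }
  # scope: edit must lie inside the intron
  if (!isIns && (co$gs < istart || co$ge > iend))
    return(emptyCall("not-intronic"))

  # transcribed-strand edit in anchored coordinates
  revc <- function(s) if (nzchar(s))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))) else s
  altT <- if (strand == "-") revc(co$altCore) else co$altCore
  if (isIns) {
    q <- min(aOf(co$gs - 1L), aOf(co$gs))  # insertion between q and q+1
    aFrom <- q + 1L; aTo <- q              # empty ref interval
  } else {
    bounds <- sort(aOf(c(co$gs, co$ge)))
    aFrom <- bounds[1L]; aTo <- bounds[2L]
  }

  # window on the transcribed strand, REF frame
  anchor5 <- if (is.na(bp2)) bp1 else bp2
  pad <- nchar(co$refCore) + nchar(altT) + 4L
  A0 <- max(-L, min(anchor5, aFrom) - pad)
  refWin <- strsplit(substr(iseq, L + A0 + 1L, L), "", fixed = TRUE)[[1L]]
  refAnch <- seq.int(A0, -1L)
  idx <- function(a) a - A0 + 1L

  # sanity: REF alleles must match the reference genome
  if (!isIns) {
    obs <- paste(refWin[idx(aFrom):idx(aTo)], collapse = "")
    expd <- if (strand == "-") revc(co$refCore) else co$refCore
    if (obs != expd) return(emptyCall("ref-mismatch"))
  }

  isComplex <- nzchar(co$refCore) && nzchar(altT) &&
    !(nchar(co$refCore) == nchar(altT))
  if (isIns) {
    at <- idx(aFrom - 1L)   # index of base q
    altWin <- append(refWin, strsplit(altT, "")[[1L]], after = at)
    origin <- append(refAnch, rep(NA_integer_, nchar(altT)), after = at)
    edited <- append(rep(FALSE, length(refWin)), rep(TRUE, nchar(altT)), after = at)
  } else if (!nzchar(altT)) {          # deletion
    keep <- -(idx(aFrom):idx(aTo))
    altWin <- refWin[keep]; origin <- refAnch[keep]
    edited <- rep(FALSE, length(altWin))
  } else if (nchar(co$refCore) == nchar(altT)) {  # snv / mnv
    altWin <- refWin; origin <- refAnch
    rng <- idx(aFrom):idx(aTo)
    altWin[rng] <- strsplit(altT, "")[[1L]]
    edited <- rep(FALSE, length(altWin)); edited[rng] <- altWin[rng] != refWin[rng]
    origin[rng][edited[rng]] <- refAnch[rng][edited[rng]]  # origin kept; edited marks it
  } else {                              # complex, unequal lengths
    rng <- idx(aFrom):idx(aTo)
    altWin <- c(refWin[seq_len(rng[1L] - 1L)], strsplit(altT, "")[[1L]],
                refWin[seq.int(rng[length(rng)] + 1L, length(refWin))])
    origin <- c(refAnch[seq_len(rng[1L] - 1L)], rep(NA_integer_, nchar(altT)),
                refAnch[seq.int(rng[length(rng)] + 1L, length(refWin))])
    edited <- is.na(origin)
  }
  Lw <- length(altWin)
  altAnch <- seq_len(Lw) - Lw - 1L
  bp1Alt <- altAnch[match(bp1, origin)]
  bp2Alt <- if (!is.na(bp2)) altAnch[match(bp2, origin)] else NA_integer_
  if (is.na(bp1Alt)) return(emptyCall("BP-variant (BPHunter scope)"))
  refCharAt <- function(a) {
    i <- a - A0 + 1L
    if (is.na(a) || i < 1L || i > length(refWin)) "N" else refWin[i]
  }

  calls <- list()
  for (i in seq_len(Lw - 1L)) {
    if (altWin[i] != "A" || altWin[i + 1L] != "G") next
    aA <- altAnch[i]; gA <- altAnch[i + 1L]
    zone <- if (aA >= bp1Alt + 1L && gA <= -4L) "ZONE 1"
            else if (!is.na(bp2Alt) && aA >= bp2Alt + 1L && gA <= bp1Alt - 1L) "ZONE 2"
            else next
    o1 <- origin[i]; o2 <- origin[i + 1L]
    e1 <- edited[i]; e2 <- edited[i + 1L]
    junction <- !is.na(o1) && !is.na(o2) && (o2 > o1 + 1L)
    if (!(e1 || e2 || is.na(o1) || is.na(o2) || junction)) next  # untouched AG
    isNew <-
      if (is.na(o1) && is.na(o2)) TRUE
      else if (is.na(o1)) refCharAt(o2 - 1L) != "A"
      else if (is.na(o2)) refCharAt(o1 + 1L) != "G"
      else if (junction) refCharAt(o1 + 1L) != "G" && refCharAt(o2 - 1L) != "A"
      else !(refCharAt(o1) == "A" && refCharAt(o2) == "G")
    if (!isNew) next
    mech <- if (isComplex) "complex"
      else if (is.na(o1) && is.na(o2)) "ins-contains-AG"
      else if (is.na(o1) || is.na(o2)) "ins-junction"
      else if (junction) "del-junction"
      else if (e1 && e2) "complex"
      else if (e1) "snv-new-A"
      else "snv-new-G"
    yag <- if (i > 1L) altWin[i - 1L] %in% c("C", "T") else FALSE
    bpAnchorAlt <- if (zone == "ZONE 1") bp1Alt else bp2Alt
    d <- computeDistances(aA, gA, bpAnchorAlt)
    hr <- classifyRisk(zone, d$bpDist)
    calls[[length(calls) + 1L]] <- data.frame(
      zone = zone, a_pos = aA, g_pos = gA, mechanism = mech, yag = yag,
      bp_dist = d$bpDist, acc_dist = d$accDist, high_risk = hr,
      score = scoreCall(zone, hr, yag, d$accDist),
      retained_seq = if (i + 2L <= Lw) paste(altWin[seq.int(i + 2L, Lw)], collapse = "") else "",
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(emptyCall(NA_character_))
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  out[!duplicated(out[, c("a_pos", "g_pos")]), , drop = FALSE]
}

#' Scan a VCF against the splice database
#'
#' One output row per (variant x transcript-intron) AG-gain, with the
#' standard annotation columns (VAR_TYPE, GENE, TRANSCRIPT_IVS, CANONICAL,
#' AGAIN_ZONE, AGAIN_YAG, AGAIN_BP_DIST, AGAIN_ACC_DIST, AGAIN_HIGHRISK,
#' AGAIN_SCORE and the protein-outcome columns), "YES"/"NO" booleans, "." for
#' absent values, deterministic row order (coordinate, then transcript).
#' Row-level failures (reference mismatch, rejected variants) are collected
#' in the `rejected` attribute; a missing genome contig is fatal.
#'
#' @param db a [SpliceDb-class].
#' @param vcf path to a VCF file, or a data.frame with columns CHROM, POS,
#'   ID, REF, ALT.
#' @param transcriptMode "all" or "canonical".
#' @param scoreMin minimum score to report.
#' @param highRiskOnly restrict to high-risk calls.
#' @param protein compute protein outcomes (columns are "." when off).
#' @return annotated data.frame; attribute `rejected` holds reason-coded
#'   exclusions.
#' @export
scanVariants <- function(db, vcf, transcriptMode = c("all", "canonical"),
                         scoreMin = 1L, highRiskOnly = FALSE, protein = TRUE) {
  transcriptMode <- match.arg(transcriptMode)
  df <- if (is.character(vcf)) readVcfTable(vcf) else as.data.frame(vcf)
  ctgs <- unique(as.character(df[[1L]]))
  missing <- setdiff(ctgs, names(db@genome))
  if (length(missing) && nrow(df))
    stop(sprintf("genome is missing contig(s): %s", paste(missing, collapse = ", ")))
  nv <- normalizeVariants(df)

  keepTx <- names(db@transcripts)
  if (transcriptMode == "canonical") {
    keepTx <- keepTx[vapply(db@transcripts, function(t) t@isCanonical, logical(1))]
  }
  im <- S4Vectors::mcols(db@introns)
  rows <- list(); rejected <- list()
  for (i in seq_len(nrow(nv))) {
    v <- nv[i, ]
    span <- GenomicRanges::GRanges(v$chrom,
      IRanges::IRanges(v$pos, v$pos + max(nchar(v$ref), 1L) - 1L))
    hits <- GenomicRanges::findOverlaps(span, db@introns, ignore.strand = TRUE)
    hitIdx <- S4Vectors::subjectHits(hits)
    hitIdx <- hitIdx[im$transcript_id[hitIdx] %in% keepTx]
    for (j in hitIdx) {
      txid <- im$transcript_id[j]; ivs <- im$intron_index[j]
      calls <- detectAgGain(db, txid, ivs, v$pos, v$ref, v$alt)
      reason <- attr(calls, "reason")
      if (!nrow(calls)) {
        if (!is.na(reason) && !reason %in% "no-BP")
          rejected[[length(rejected) + 1L]] <- data.frame(
            chrom = v$chrom, pos = v$pos, id = v$id, transcript_id = txid,
            intron_index = ivs, reason = reason, stringsAsFactors = FALSE)
        next
      }
      tx <- db@transcripts[[txid]]
      ivsTag <- sprintf("%s_IVS%d", txid, ivs)
      for (k in seq_len(nrow(calls))) {
        cl <- calls[k, ]
        prot <- list(wt = ".", newSeq = ".", newHgvs = ".",
                     skipSeq = ".", skipHgvs = ".")
        if (protein)
          prot <- proteinColumns(db, tx, ivs, cl$retained_seq)
        rows[[length(rows) + 1L]] <- data.frame(
          CHROM = v$chrom, POS = v$pos, ID = v$id, REF = v$ref, ALT = v$alt,
          VAR_TYPE = v$var_type, GENE = tx@geneSymbol,
          TRANSCRIPT_IVS = ivsTag,
          CANONICAL = if (tx@isCanonical) ivsTag else ".",
          AGAIN_ZONE = cl$zone,
          AGAIN_YAG = if (cl$yag) "YES" else "NO",
          AGAIN_BP_DIST = cl$bp_dist, AGAIN_ACC_DIST = cl$acc_dist,
          AGAIN_HIGHRISK = if (cl$high_risk) "YES" else "NO",
          AGAIN_SCORE = cl$score,
          PROT_SEQ_WT = prot$wt, PROT_SEQ_NEW_ACC = prot$newSeq,
          HGVS_NEW_ACC = prot$newHgvs, PROT_SEQ_EXON_SKIP = prot$skipSeq,
          HGVS_EXON_SKIP = prot$skipHgvs,
          MECHANISM = cl$mechanism, A_POS = cl$a_pos, G_POS = cl$g_pos,
          ACCEPTOR_AG = im$acceptor_ag[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else emptyScanTable()
  if (nrow(out)) {
    out <- out[out$AGAIN_SCORE >= scoreMin, , drop = FALSE]
    if (highRiskOnly) out <- out[out$AGAIN_HIGHRISK == "YES", , drop = FALSE]
    out <- out[order(out$CHROM, out$POS, out$TRANSCRIPT_IVS, out$A_POS), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejected") <- if (length(rejected))
    do.call(rbind, c(rejected, list(make.row.names = FALSE)))
  else data.frame(chrom = character(), pos = integer(), id = character(),
                  transcript_id = character(), intron_index = integer(),
                  reason = character())
  out
}

scanColumns <- c("CHROM", "POS", "ID", "REF", "ALT", "VAR_TYPE", "GENE",
  "TRANSCRIPT_IVS", "CANONICAL", "AGAIN_ZONE", "AGAIN_YAG", "AGAIN_BP_DIST",
  "AGAIN_ACC_DIST", "AGAIN_HIGHRISK", "AGAIN_SCORE", "PROT_SEQ_WT",
  "PROT_SEQ_NEW_ACC", "HGVS_NEW_ACC", "PROT_SEQ_EXON_SKIP", "HGVS_EXON_SKIP")

emptyScanTable <- function() {
  cols <- c(scanColumns, "MECHANISM", "A_POS", "G_POS", "ACCEPTOR_AG")
  out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  for (nm in c("POS", "AGAIN_BP_DIST", "AGAIN_ACC_DIST", "AGAIN_SCORE",
               "A_POS", "G_POS")) out[[nm]] <- integer()
  out$ACCEPTOR_AG <- logical()
  out
}

#' Write a scan table as TSV with the standard column set
#'
#' @param tab scan table from [scanVariants()].
#' @param path output file.
#' @param extended include the mechanism/coordinate extras after the standard
#'   columns.
#' @export
writeScanTsv <- function(tab, path, extended = FALSE) {
  cols <- if (extended) names(tab) else scanColumns
  utils::write.table(tab[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

# minimal-table view of a VCF file via VariantAnnotation
readVcfTable <- function(path) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  if (!length(v))
    return(data.frame(CHROM = character(), POS = integer(), ID = character(),
                      REF = character(), ALT = character()))
  rr <- SummarizedExperiment::rowRanges(v)
  altl <- VariantAnnotation::alt(v)
  alts <- vapply(seq_along(v), function(i)
    paste(as.character(altl[[i]]), collapse = ","), character(1))
  data.frame(CHROM = as.character(GenomicRanges::seqnames(rr)),
             POS = GenomicRanges::start(rr),
             ID = names(rr),
             REF = as.character(VariantAnnotation::ref(v)),
             ALT = alts, stringsAsFactors = FALSE)
}
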