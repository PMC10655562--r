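#' @include AllClasses.R
NULL

# ---- transcript-level plumbing ----------------------------------------------

# spliced transcribed-strand mRNA of a transcript
txMrna <- function(db, tx) {
  paste(vapply(seq_along(tx@exons), function(i) exonSeq(db, tx, i), character(1)),
        collapse = "")
}

exonSeq <- function(db, tx, i) {
  ex <- tx@exons[i]
  s <- Biostrings::subseq(db@genome[[tx@chrom]], IRanges::start(ex), IRanges::end(ex))
  if (tx@strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# transcript coordinate (1-based, transcription direction) of a genomic position
txCoord <- function(tx, gpos) {
  off <- 0L
  for (i in seq_along(tx@exons)) {
    s <- IRanges::start(tx@exons[i]); e <- IRanges::end(tx@exons[i])
    if (gpos >= s && gpos <= e) {
      within <- if (tx@strand == "+") gpos - s + 1L else e - gpos + 1L
      return(off + within)
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

# codon-by-codon translation until the first stop; trailing partial codon dropped
translateToStop <- function(seq) {
  n <- nchar(seq) %/% 3L
  prot <- character(0L)
  stopAt <- NA_integer_
  for (k in seq_len(n)) {
    codon <- substr(seq, 3L * k - 2L, 3L * k)
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa) || is.na(aa)) aa <- "X"
    if (aa == "*") { stopAt <- k; break }
    prot <- c(prot, aa)
  }
  list(protein = paste(prot, collapse = ""), stopCodon = stopAt,
       hasStop = !is.na(stopAt))
}

# ---- missplicing scenarios ---------------------------------------------------

#' Mature transcript and protein for the new-acceptor scenario
#'
#' The mature transcript keeps all exons and inserts the retained intronic
#' tail (the `accDist` nucleotides 3' of the created G, taken from the mutant
#' intron) between the flanking exons. A variant 5' of the start codon or 3'
#' of the stop codon leaves the protein unchanged.
#'
#' @param db a [SpliceDb-class].
#' @param tx a [TranscriptModel-class].
#' @param intronIndex intron hosting the AG-gain (transcription order).
#' @param retainedSeq transcribed-strand retained tail of the mutant intron.
#' @return list: protein, hgvs, flags (character vector), mature (mRNA),
#'   startStatus.
#' @export
assembleNewAcceptorOutcome <- function(db, tx, intronIndex, retainedSeq) {
  wt <- wildTypeProtein(db, tx)
  insLen <- nchar(retainedSeq)
  upLen <- sum(IRanges::width(tx@exons[seq_len(intronIndex)]))
  insAt <- upLen + 1L                       # first inserted base, tx coords
  mrna <- txMrna(db, tx)
  mature <- paste0(substr(mrna, 1L, upLen), retainedSeq,
                   substr(mrna, upLen + 1L, nchar(mrna)))
  cs <- txCoord(tx, tx@cdsStart); ce <- txCoord(tx, tx@cdsEnd)
  if (is.na(cs))
    return(list(protein = "", hgvs = ".", flags = "non-coding",
                mature = mature, startStatus = "unknown"))
  if (insAt > ce)                            # 3' UTR intron
    return(list(protein = wt, hgvs = "p.(=)", flags = character(),
                mature = mature, startStatus = "intact"))
  if (insAt <= cs)                           # 5' UTR intron: start shifts, intact
    return(list(protein = wt, hgvs = "p.(=)", flags = character(),
                mature = mature, startStatus = "intact"))
  tr <- translateToStop(substr(mature, cs, nchar(mature)))
  inFrame <- insLen %% 3L == 0L
  flags <- if (inFrame) "in_frame" else "frameshift"
  stopIns <- FALSE
  if (tr$hasStop) {
    stopTx <- cs + 3L * tr$stopCodon - 1L    # last base of the stop codon
    stopTx0 <- stopTx - 2L
    if (stopTx >= insAt && stopTx0 <= insAt + insLen - 1L) {
      stopIns <- TRUE; flags <- c(flags, "stop_in_insertion")
    }
  } else flags <- c(flags, "no_stop")
  list(protein = tr$protein,
       hgvs = hgvsProtein(wt, tr$protein, frameshift = !inFrame,
                          stopInInsertion = stopIns && inFrame),
       flags = flags, mature = mature, startStatus = "intact")
}

#' Mature transcript and protein for the exon-skip scenario
#'
#' Omits the exon downstream of the intron (exon intronIndex+1 in
#' transcription order). Skipping the exon that harbours the start codon is
#' reported as gross transcript ablation (p.0?); skipping an exon entirely in
#' the UTRs leaves the protein unchanged; skipping the stop-codon exon sets
#' the stop_lost flag but still emits a product.
#'
#' @inheritParams assembleNewAcceptorOutcome
#' @return list: protein, hgvs, flags, mature, startStatus.
#' @export
assembleExonSkipOutcome <- function(db, tx, intronIndex) {
  n <- length(tx@exons)
  k <- intronIndex + 1L
  stopifnot(k <= n)
  wt <- wildTypeProtein(db, tx)
  w <- IRanges::width(tx@exons)
  es <- sum(w[seq_len(k - 1L)]) + 1L; ee <- es + w[k] - 1L   # tx coords of exon k
  mrna <- txMrna(db, tx)
  mature <- paste0(substr(mrna, 1L, es - 1L), substr(mrna, ee + 1L, nchar(mrna)))
  cs <- txCoord(tx, tx@cdsStart); ce <- txCoord(tx, tx@cdsEnd)
  if (is.na(cs))
    return(list(protein = "", hgvs = ".", flags = "non-coding",
                mature = mature, startStatus = "unknown"))
  if (cs >= es && cs <= ee)
    return(list(protein = "", hgvs = "p.0?", flags = "transcript_ablation",
                mature = mature, startStatus = "ablated"))
  if (ee < cs || es > ce)                    # UTR exon
    return(list(protein = wt, hgvs = "p.(=)", flags = character(),
                mature = mature, startStatus = "intact"))
  delNt <- min(ee, ce) - max(es, cs) + 1L    # CDS nucleotides removed
  inFrame <- delNt %% 3L == 0L
  stopLost <- ce >= es && ce <= ee
  tr <- translateToStop(substr(mature, cs, nchar(mature)))
  flags <- c(if (inFrame) "in_frame" else "frameshift",
             if (stopLost) "stop_lost",
             if (!tr$hasStop) "no_stop")
  list(protein = tr$protein,
       hgvs = hgvsProtein(wt, tr$protein, frameshift = !inFrame),
       flags = flags, mature = mature, startStatus = "intact")
}

#' Wild-type protein of a transcript
#'
#' @inheritParams assembleNewAcceptorOutcome
#' @return one-letter protein string (empty for non-coding models).
#' @export
wildTypeProtein <- function(db, tx) {
  cs <- txCoord(tx, tx@cdsStart)
  if (is.na(cs)) return("")
  translateToStop(substr(txMrna(db, tx), cs, nchar(txMrna(db, tx))))$protein
}

# Box-1 protein columns for one call
proteinColumns <- function(db, tx, intronIndex, retainedSeq) {
  wt <- wildTypeProtein(db, tx)
  newAcc <- assembleNewAcceptorOutcome(db, tx, intronIndex, retainedSeq)
  skip <- if (intronIndex + 1L <= length(tx@exons))
    assembleExonSkipOutcome(db, tx, intronIndex)
  else list(protein = ".", hgvs = ".")
  dot <- function(x) if (!nzchar(x)) "." else x
  list(wt = dot(wt), newSeq = dot(newAcc$protein), newHgvs = dot(newAcc$hgvs),
       skipSeq = dot(skip$protein), skipHgvs = dot(skip$hgvs))
}
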