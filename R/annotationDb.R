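#' @include AllClasses.R
NULL

# ---- 3'-anchored intron coordinates ------------------------------------------
# The last transcribed base of an intron is offset -1, the second-to-last -2,
# and so on; branchpoints, zones and AG-gain calls all live in this frame.

#' Convert 3'-anchored intron offsets to genomic positions
#'
#' @param start,end genomic span of the intron (1-based inclusive).
#' @param strand "+" or "-".
#' @param offset negative integer offset(s); -1 is the last transcribed base.
#' @return genomic position(s), 1-based.
#' @export
anchoredToGenomic <- function(start, end, strand, offset) {
  stopifnot(all(offset < 0))
  if (strand == "+") end + offset + 1L else start - offset - 1L
}

#' Convert genomic positions to 3'-anchored intron offsets
#'
#' @inheritParams anchoredToGenomic
#' @param pos genomic position(s) inside the intron.
#' @return negative integer offset(s).
#' @export
genomicToAnchored <- function(start, end, strand, pos) {
  if (strand == "+") pos - end - 1L else start - pos - 1L
}

# ---- GTF loading -------------------------------------------------------------

#' Load protein-coding gene models from a GENCODE-dialect GTF
#'
#' Retains transcripts passing the three GENCODE confidence filters used to
#' define the intron universe: `transcript_type == "protein_coding"`,
#' annotation `tag` containing "basic", and `level` 1 or 2. Exons are ordered
#' in transcription direction and the coding span is located from CDS (plus
#' stop_codon, which GENCODE excludes from CDS) features.
#'
#' @param gtf path to a GTF file.
#' @param proteinCodingOnly,basicOnly,maxLevel filter toggles; defaults apply
#'   all three filters.
#' @return named list of [TranscriptModel-class] objects.
#' @export
loadGeneModels <- function(gtf, proteinCodingOnly = TRUE, basicOnly = TRUE,
                           maxLevel = 2L) {
  lines <- readLines(gtf)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                 bad, nf[which(nf != 9L)[1L]]))
  }
  gr <- rtracklayer::import(gtf, format = "gtf")
  md <- S4Vectors::mcols(gr)
  getcol <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else
    rep(NA_character_, length(gr))
  txId   <- getcol("transcript_id")
  txType <- getcol("transcript_type")
  tag    <- getcol("tag")
  level  <- getcol("level")
  gene   <- getcol("gene_name")
  type   <- as.character(md$type)

  isTx <- type == "transcript" & !is.na(txId)
  keep <- rep(TRUE, sum(isTx))
  txRows <- which(isTx)
  if (proteinCodingOnly) keep <- keep & txType[txRows] %in% "protein_coding"
  if (basicOnly)         keep <- keep & grepl("basic", tag[txRows])
  keep <- keep & suppressWarnings(as.integer(level[txRows])) <= maxLevel
  keep[is.na(keep)] <- FALSE
  keptIds <- txId[txRows][keep]

  out <- list()
  for (id in keptIds) {
    rows <- which(txId == id)
    exRows <- rows[type[rows] == "exon"]
    if (!length(exRows)) {
      warning(sprintf("transcript %s has zero exons; skipped", id))
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(gr))[exRows[1L]]
    strnd <- as.character(GenomicRanges::strand(gr))[exRows[1L]]
    ex <- IRanges::IRanges(GenomicRanges::start(gr)[exRows],
                           GenomicRanges::end(gr)[exRows])
    ord <- order(IRanges::start(ex), decreasing = (strnd == "-"))
    ex <- ex[ord]
    cdsRows  <- rows[type[rows] == "CDS"]
    stopRows <- rows[type[rows] == "stop_codon"]
    cdsStart <- cdsEnd <- NA_integer_
    if (length(cdsRows)) {
      cs <- GenomicRanges::start(gr)[cdsRows]; ce <- GenomicRanges::end(gr)[cdsRows]
      ss <- GenomicRanges::start(gr)[stopRows]; se <- GenomicRanges::end(gr)[stopRows]
      if (strnd == "+") {
        cdsStart <- min(cs)
        cdsEnd   <- max(c(ce, se))
      } else {
        cdsStart <- max(ce)
        cdsEnd   <- min(c(cs, ss))
      }
    }
    out[[id]] <- methods::new("TranscriptModel",
      transcriptId = id,
      geneSymbol   = if (is.na(gene[rows[1L]])) id else gene[rows[1L]],
      chrom        = chrom,
      strand       = strnd,
      exons        = ex,
      cdsStart     = as.integer(cdsStart),
      cdsEnd       = as.integer(cdsEnd))
  }
  out
}

#' Derive introns from a transcript model
#'
#' Introns are the gaps between adjacent exons, numbered 1..n-1 in
#' transcription direction (IVS numbering). Single-exon transcripts yield an
#' empty result.
#'
#' @param tx a [TranscriptModel-class].
#' @return data.frame with transcript_id, intron_index, chrom, start, end,
#'   strand, length.
#' @export
extractIntrons <- function(tx) {
  ex <- tx@exons
  n <- length(ex)
  if (n < 2L)
    return(data.frame(transcript_id = character(), intron_index = integer(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), length = integer()))
  s <- IRanges::start(ex); e <- IRanges::end(ex)
  if (tx@strand == "+") {
    istart <- e[-n] + 1L; iend <- s[-1L] - 1L
  } else {
    istart <- e[-1L] + 1L; iend <- s[-n] - 1L
  }
  data.frame(transcript_id = tx@transcriptId, intron_index = seq_len(n - 1L),
             chrom = tx@chrom, start = istart, end = iend, strand = tx@strand,
             length = iend - istart + 1L)
}

# ---- Branchpoints ------------------------------------------------------------

#' Load branchpoint records and map them into intron offsets
#'
#' Accepts either a 3-column offset table (transcript_id, intron_index,
#' offset) or a 6-column BED (chrom, 0-based start, end, name =
#' "transcript|intron|rank", score, strand) whose positions are mapped into
#' 3'-anchored offsets against the supplied introns. Records outside the
#' [-100, -3] acceptor-upstream window are discarded; surviving records are
#' ranked per intron by proximity to the acceptor (rank 1 = closest), ties
#' broken by input order.
#'
#' @param bp path to a TSV/BED file, or a data.frame in either layout.
#' @param introns intron table/`GRanges` from the database (needed for BED
#'   input and validation).
#' @return data.frame: transcript_id, intron_index, offset, rank.
#' @export
loadBranchpoints <- function(bp, introns = NULL) {
  if (is.character(bp)) {
    bp <- utils::read.table(bp, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
  }
  bp <- as.data.frame(bp)
  if (ncol(bp) >= 6L && is.character(bp[[4L]]) &&
      all(grepl("|", bp[[4L]], fixed = TRUE))) {
    # BED layout
    if (is.null(introns)) stop("BED branchpoint input requires introns")
    it <- intronFrame(introns)
    parts <- strsplit(bp[[4L]], "|", fixed = TRUE)
    res <- vector("list", nrow(bp))
    for (i in seq_len(nrow(bp))) {
      txid <- parts[[i]][1L]; ivs <- as.integer(parts[[i]][2L])
      pos <- as.integer(bp[[3L]])[i]  # BED end = 1-based position
      row <- it[it$transcript_id == txid & it$intron_index == ivs, , drop = FALSE]
      if (!nrow(row)) { warning(sprintf("branchpoint row %d: unknown intron %s_IVS%d; skipped", i, txid, ivs)); next }
      if (bp[[6L]][i] != row$strand) { warning(sprintf("branchpoint row %d: strand mismatch; skipped", i)); next }
      if (pos < row$start || pos > row$end) { warning(sprintf("branchpoint row %d: position outside intron; skipped", i)); next }
      res[[i]] <- data.frame(transcript_id = txid, intron_index = ivs,
        offset = genomicToAnchored(row$start, row$end, row$strand, pos))
    }
    bp <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(bp)) bp <- data.frame(transcript_id = character(),
                                      intron_index = integer(), offset = integer())
  } else {
    names(bp)[1:3] <- c("transcript_id", "intron_index", "offset")
    bp$intron_index <- as.integer(bp$intron_index)
    bp$offset <- as.integer(bp$offset)
  }
  bp <- bp[bp$offset <= -3L & bp$offset >= -100L, , drop = FALSE]
  if (!nrow(bp))
    return(data.frame(transcript_id = character(), intron_index = integer(),
                      offset = integer(), rank = integer()))
  bp$.in <- seq_len(nrow(bp))
  key <- paste(bp$transcript_id, bp$intron_index)
  bp <- bp[order(key, -bp$offset, bp$.in), , drop = FALSE]
  bp$rank <- stats::ave(bp$offset, paste(bp$transcript_id, bp$intron_index),
                        FUN = seq_along)
  bp$rank <- as.integer(bp$rank)
  bp$.in <- NULL
  rownames(bp) <- NULL
  bp
}

# normalize introns argument (GRanges or data.frame) to a plain frame
intronFrame <- function(introns) {
  if (is(introns, "GRanges")) {
    data.frame(transcript_id = S4Vectors::mcols(introns)$transcript_id,
               intron_index = S4Vectors::mcols(introns)$intron_index,
               chrom = as.character(GenomicRanges::seqnames(introns)),
               start = GenomicRanges::start(introns),
               end = GenomicRanges::end(introns),
               strand = as.character(GenomicRanges::strand(introns)),
               length = GenomicRanges::width(introns),
               stringsAsFactors = FALSE)
  } else as.data.frame(introns)
}

# ---- Canonical transcripts ---------------------------------------------------

#' Mark canonical transcripts from a MANE-style identifier list
#'
#' Version suffixes are stripped from both sides before matching, since MANE
#' and GENCODE versions drift.
#'
#' @param txs named list of [TranscriptModel-class].
#' @param maneList character vector of transcript IDs, or a path to a
#'   one-ID-per-line text file.
#' @param mode "all" keeps every transcript (flagged); "canonical" drops
#'   non-canonical transcripts.
#' @return the transcript list, flagged (and possibly subset).
#' @export
selectCanonical <- function(txs, maneList, mode = c("all", "canonical")) {
  mode <- match.arg(mode)
  if (length(maneList) == 1L && is.character(maneList) && file.exists(maneList))
    maneList <- readLines(maneList)
  maneList <- maneList[nzchar(maneList)]
  stripv <- function(x) sub("\\.[0-9]+$", "", x)
  canon <- stripv(maneList)
  hits <- stripv(names(txs)) %in% canon
  if (!any(hits)) {
    if (mode == "canonical")
      stop("no transcript matches the canonical list; rerun in all-transcript mode")
    warning("canonical list has empty intersection with transcripts; proceeding with all-transcript mode")
  }
  for (i in which(hits)) txs[[i]]@isCanonical <- TRUE
  if (mode == "canonical") txs[hits] else txs
}

# ---- Database assembly -------------------------------------------------------

#' Build the intron-level splice annotation database
#'
#' Loads the genome, gene models and branchpoints, derives introns, caches
#' each intron's transcribed-strand sequence, flags non-AG acceptors
#' (kept, but calls in them carry the flag), and precomputes the per-intron
#' zone table from the rank-1/rank-2 branchpoints.
#'
#' @param genome path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param gtf path to a GENCODE-dialect GTF, or a prebuilt transcript list.
#' @param bp branchpoint input (see [loadBranchpoints()]).
#' @param canonical optional canonical-list input (see [selectCanonical()]).
#' @param transcriptMode "all" or "canonical".
#' @return a [SpliceDb-class] object.
#' @export
buildSpliceDb <- function(genome, gtf, bp, canonical = NULL,
                          transcriptMode = c("all", "canonical")) {
  transcriptMode <- match.arg(transcriptMode)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  txs <- if (is.list(gtf)) gtf else loadGeneModels(gtf)
  if (!is.null(canonical)) txs <- selectCanonical(txs, canonical, transcriptMode)

  itl <- lapply(txs, extractIntrons)
  it <- do.call(rbind, c(itl, list(make.row.names = FALSE)))
  if (is.null(it) || !nrow(it))
    stop("no multi-exon transcript: no introns to annotate")
  if (any(bad <- it$length < 4L)) {
    warning(sprintf("%d intron(s) shorter than 4 nt dropped", sum(bad)))
    it <- it[!bad, , drop = FALSE]
  }
  missing <- setdiff(unique(it$chrom), names(genome))
  if (length(missing))
    stop(sprintf("genome is missing contig(s): %s", paste(missing, collapse = ", ")))
  seqs <- character(nrow(it))
  for (i in seq_len(nrow(it))) {
    s <- Biostrings::subseq(genome[[it$chrom[i]]], it$start[i], it$end[i])
    if (it$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  accAg <- substr(seqs, nchar(seqs) - 1L, nchar(seqs)) == "AG"
  if (any(!accAg))
    warning(sprintf("%d intron(s) lack the canonical terminal AG; kept and flagged",
                    sum(!accAg)))
  gr <- GenomicRanges::GRanges(it$chrom, IRanges::IRanges(it$start, it$end),
                               strand = it$strand)
  S4Vectors::mcols(gr)$transcript_id <- it$transcript_id
  S4Vectors::mcols(gr)$intron_index  <- it$intron_index
  S4Vectors::mcols(gr)$seq           <- seqs
  S4Vectors::mcols(gr)$acceptor_ag   <- accAg

  bpdf <- loadBranchpoints(bp, gr)
  known <- paste(it$transcript_id, it$intron_index)
  drop <- !paste(bpdf$transcript_id, bpdf$intron_index) %in% known
  if (any(drop)) {
    warning(sprintf("%d branchpoint record(s) not inside any known intron; skipped",
                    sum(drop)))
    bpdf <- bpdf[!drop, , drop = FALSE]
  }
  db <- methods::new("SpliceDb", genome = genome, transcripts = txs,
                     introns = gr, branchpoints = bpdf,
                     zoneTable = data.frame())
  db@zoneTable <- buildZoneTable(db)
  db
}

# Per-intron zone arithmetic table; introns without a branchpoint are recorded
# with a reason code so coverage can be accounted for.
buildZoneTable <- function(db) {
  it <- intronFrame(db@introns)
  bp <- db@branchpoints
  rows <- vector("list", nrow(it))
  for (i in seq_len(nrow(it))) {
    b <- bp[bp$transcript_id == it$transcript_id[i] &
            bp$intron_index == it$intron_index[i], , drop = FALSE]
    bp1 <- if (any(b$rank == 1L)) b$offset[b$rank == 1L] else NA_integer_
    bp2 <- if (any(b$rank == 2L)) b$offset[b$rank == 2L] else NA_integer_
    if (is.na(bp1)) {
      rows[[i]] <- data.frame(transcript_id = it$transcript_id[i],
        intron_index = it$intron_index[i], bp1 = NA_integer_, bp2 = NA_integer_,
        z1_from = NA_integer_, z1_to = NA_integer_, z2_from = NA_integer_,
        z2_to = NA_integer_, z3_from = NA_integer_, z3_to = NA_integer_,
        hr_from = NA_integer_, hr_to = NA_integer_, z3_truncated = NA,
        skipped = "no-BP")
      next
    }
    z <- delineateZones(bp1, bp2, intronLength = it$length[i])
    rows[[i]] <- data.frame(transcript_id = it$transcript_id[i],
      intron_index = it$intron_index[i], bp1 = z@bp1, bp2 = z@bp2,
      z1_from = z@zone1[1L], z1_to = z@zone1[2L],
      z2_from = z@zone2[1L], z2_to = z@zone2[2L],
      z3_from = z@zone3[1L], z3_to = z@zone3[2L],
      hr_from = z@highRisk[1L], hr_to = z@highRisk[2L],
      z3_truncated = z@zone3Truncated, skipped = NA_character_)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
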