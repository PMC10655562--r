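#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement subseq
NULL

#' TranscriptModel: one protein-coding transcript
#'
#' Exon intervals are stored 1-based inclusive and ordered in transcription
#' direction (decreasing genomic coordinate on the minus strand). The CDS span
#' is recorded as the genomic coordinate of the first base of the start codon
#' (`cdsStart`) and the last base of the stop codon (`cdsEnd`), both in
#' transcription direction, or `NA` for non-coding models.
#'
#' @slot transcriptId character, transcript identifier (version retained).
#' @slot geneSymbol character, gene symbol.
#' @slot chrom character, chromosome name.
#' @slot strand character, "+" or "-".
#' @slot exons [IRanges::IRanges] in transcription order.
#' @slot cdsStart,cdsEnd integer genomic coordinates of the coding span.
#' @slot isCanonical logical, membership in the canonical (MANE-style) list.
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneSymbol   = "character",
    chrom        = "character",
    strand       = "character",
    exons        = "IRanges",
    cdsStart     = "integer",
    cdsEnd       = "integer",
    isCanonical  = "logical"
  ),
  prototype(cdsStart = NA_integer_, cdsEnd = NA_integer_, isCanonical = FALSE)
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (length(ex) < 1L) msg <- c(msg, "transcript must have at least one exon")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (length(ex) > 1L) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    ok <- if (object@strand == "+") all(diff(s) > 0) && all(e[-length(e)] < s[-1L])
          else all(diff(s) < 0) && all(s[-length(s)] > e[-1L])
    if (!ok) msg <- c(msg, "exons must be non-overlapping and ordered in transcription direction")
  }
  if (!is.na(object@cdsStart)) {
    inEx <- any(object@cdsStart >= IRanges::start(ex) & object@cdsStart <= IRanges::end(ex))
    if (!inEx) msg <- c(msg, "cdsStart must lie within the exon union")
  }
  if (length(msg)) msg else TRUE
})

#' IntronZones: the three analysis intervals of one intron
#'
#' All coordinates are 3'-anchored intron offsets (last intron base = -1).
#' Zone 1 runs from BP1+1 to ACC-4; zone 2 (multi-BP introns only) from BP2+1
#' to BP1-1; zone 3 is the fixed 30-nt control window ending immediately 5' of
#' the zone anchor (BP1, or BP2 when a second branchpoint exists). The
#' high-risk interval [BP1+8, ACC-4] is the AG/YAG-depleted core of zone 1.
#' Empty intervals are stored as `NA` bounds.
#'
#' @exportClass IntronZones
setClass("IntronZones",
  representation(
    transcriptId = "character",
    intronIndex  = "integer",
    bp1          = "integer",
    bp2          = "integer",
    zone1        = "integer",
    zone2        = "integer",
    zone3        = "integer",
    highRisk     = "integer",
    zone3Truncated = "logical"
  ),
  prototype(bp2 = NA_integer_, zone3Truncated = FALSE)
)

setValidity("IntronZones", function(object) {
  msg <- character()
  chk <- function(z, nm) {
    if (length(z) != 2L) return(sprintf("%s must be length-2 (from, to)", nm))
    if (!any(is.na(z)) && z[1L] > z[2L]) return(sprintf("%s bounds reversed", nm))
    NULL
  }
  for (nm in c("zone1", "zone2", "zone3", "highRisk"))
    msg <- c(msg, chk(slot(object, nm), nm))
  z1 <- object@zone1
  if (!any(is.na(z1)) && z1[2L] > -4L) msg <- c(msg, "zone1 must end at or before ACC-4")
  hr <- object@highRisk
  if (!any(is.na(hr)) && !any(is.na(z1)) && (hr[1L] < z1[1L] || hr[2L] > z1[2L]))
    msg <- c(msg, "highRisk must be contained in zone1")
  if (length(msg)) msg else TRUE
})

#' SpliceDb: intron-level annotation database
#'
#' Container tying together the reference genome, validated transcript models,
#' the derived introns (a [GenomicRanges::GRanges] carrying transcript id,
#' intron index, cached transcribed-strand sequence and an acceptor-AG flag)
#' and the branchpoint records mapped into 3'-anchored intron offsets, with
#' the per-intron zone table precomputed.
#'
#' @exportClass SpliceDb
setClass("SpliceDb",
  representation(
    genome       = "DNAStringSet",
    transcripts  = "list",
    introns      = "GRanges",
    branchpoints = "data.frame",
    zoneTable    = "data.frame"
  )
)

setValidity("SpliceDb", function(object) {
  msg <- character()
  if (length(object@transcripts) &&
      !all(vapply(object@transcripts, is, logical(1), "TranscriptModel")))
    msg <- c(msg, "transcripts must be TranscriptModel objects")
  bp <- object@branchpoints
  if (nrow(bp)) {
    if (!all(c("transcript_id", "intron_index", "offset", "rank") %in% names(bp)))
      msg <- c(msg, "branchpoints must have transcript_id/intron_index/offset/rank")
    else if (any(bp$offset > -3L | bp$offset < -100L))
      msg <- c(msg, "branchpoint offsets must lie in [-100, -3]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (is.na(object@cdsStart)) "non-coding"
         else sprintf("CDS %d..%d", object@cdsStart, object@cdsEnd)
  cat(sprintf("TranscriptModel %s (%s) %s:%s, %d exon(s), %s%s\n",
              object@transcriptId, object@geneSymbol, object@chrom,
              object@strand, length(object@exons), cds,
              if (object@isCanonical) ", canonical" else ""))
})

setMethod("show", "IntronZones", function(object) {
  fmt <- function(z) if (any(is.na(z))) "-" else sprintf("[%d, %d]", z[1L], z[2L])
  cat(sprintf("IntronZones %s_IVS%d  BP1=%d BP2=%s\n", object@transcriptId,
              object@intronIndex, object@bp1,
              if (is.na(object@bp2)) "-" else object@bp2))
  cat(sprintf("  zone1 %s  zone2 %s  zone3 %s%s  high-risk %s\n",
              fmt(object@zone1), fmt(object@zone2), fmt(object@zone3),
              if (object@zone3Truncated) " (truncated)" else "",
              fmt(object@highRisk)))
})

setMethod("show", "SpliceDb", function(object) {
  cat(sprintf("SpliceDb: %d transcript(s), %d intron(s), %d branchpoint record(s)\n",
              length(object@transcripts), length(object@introns),
              nrow(object@branchpoints)))
  nc <- sum(vapply(object@transcripts, function(t) t@isCanonical, logical(1)))
  cat(sprintf("  genome contigs: %d; canonical transcripts: %d\n",
              length(object@genome), nc))
})
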