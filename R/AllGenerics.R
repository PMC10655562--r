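#' @include AllClasses.R
NULL

#' Accessors for SpliceDb and TranscriptModel
#'
#' @param x a [SpliceDb-class] or [TranscriptModel-class] object.
#' @return `transcripts()` the named list of transcript models; `introns()`
#'   the intron `GRanges`; `branchpoints()` the branchpoint data.frame;
#'   `zoneTable()` the per-intron zone table; `genomeSeq()` the reference
#'   `DNAStringSet`; `exons()` the exon `IRanges` of a transcript.
#' @name SpliceDb-accessors
NULL

#' @rdname SpliceDb-accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @rdname SpliceDb-accessors
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))
#' @rdname SpliceDb-accessors
#' @export
setGeneric("branchpoints", function(x) standardGeneric("branchpoints"))
#' @rdname SpliceDb-accessors
#' @export
setGeneric("zoneTable", function(x) standardGeneric("zoneTable"))
#' @rdname SpliceDb-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname SpliceDb-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname SpliceDb-accessors
#' @export
setMethod("transcripts", "SpliceDb", function(x) x@transcripts)
#' @rdname SpliceDb-accessors
#' @export
setMethod("introns", "SpliceDb", function(x) x@introns)
#' @rdname SpliceDb-accessors
#' @export
setMethod("branchpoints", "SpliceDb", function(x) x@branchpoints)
#' @rdname SpliceDb-accessors
#' @export
setMethod("zoneTable", "SpliceDb", function(x) x@zoneTable)
#' @rdname SpliceDb-accessors
#' @export
setMethod("genomeSeq", "SpliceDb", function(x) x@genome)
#' @rdname SpliceDb-accessors
#' @export
setMethod("exons", "TranscriptModel", function(x) x@exons)
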