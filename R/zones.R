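#' @include AllClasses.R
NULL

#' Delineate the three analysis zones of an intron
#'
#' Zone 1 spans BP1+1 .. ACC-4 (the polypyrimidine tract in which a gained AG
#' can compete with the canonical acceptor); zone 2, present only when a
#' second branchpoint is recorded, spans BP2+1 .. BP1-1; zone 3 is the fixed
#' 30-nt control window ending immediately 5' of the zone anchor (BP1 for
#' single-BP introns, else BP2), i.e. [anchor-30, anchor-1]. The high-risk
#' interval [BP1+8, ACC-4] is empty when BP1+8 > -4. When the intron is too
#' short to hold the full zone-3 window, the window is clipped at the intron
#' 5' end and flagged truncated.
#'
#' @param bp1 rank-1 branchpoint offset (negative, 3'-anchored).
#' @param bp2 rank-2 branchpoint offset or `NA`.
#' @param intronLength intron length in nt (used to clip zone 3); `Inf`
#'   disables clipping.
#' @return an [IntronZones-class] object.
#' @export
delineateZones <- function(bp1, bp2 = NA_integer_, intronLength = Inf,
                           transcriptId = NA_character_, intronIndex = NA_integer_) {
  stopifnot(bp1 < 0, is.na(bp2) || bp2 < bp1)
  empty <- c(NA_integer_, NA_integer_)
  mk <- function(from, to) if (from > to) empty else c(as.integer(from), as.integer(to))
  zone1 <- mk(bp1 + 1L, -4L)
  zone2 <- if (is.na(bp2)) empty else mk(bp2 + 1L, bp1 - 1L)
  anchor <- if (is.na(bp2)) bp1 else bp2
  z3from <- anchor - 30L
  trunc <- FALSE
  if (is.finite(intronLength) && z3from < -intronLength) {
    z3from <- -as.integer(intronLength)
    trunc <- TRUE
  }
  zone3 <- mk(z3from, anchor - 1L)
  hr <- mk(bp1 + 8L, -4L)
  methods::new("IntronZones", transcriptId = as.character(transcriptId),
               intronIndex = as.integer(intronIndex),
               bp1 = as.integer(bp1), bp2 = as.integer(bp2),
               zone1 = zone1, zone2 = zone2, zone3 = zone3, highRisk = hr,
               zone3Truncated = trunc)
}

#' Extract the transcribed-strand sequence of a zone
#'
#' @param db a [SpliceDb-class].
#' @param transcriptId,intronIndex intron identifier.
#' @param zone length-2 integer of 3'-anchored offsets (from, to).
#' @return character sequence 5'->3' on the transcribed strand, with attribute
#'   `truncated` set when the zone was clipped at the intron 5' end.
#' @export
zoneSequence <- function(db, transcriptId, intronIndex, zone) {
  if (any(is.na(zone))) return(structure("", truncated = FALSE))
  seq <- intronSequence(db, transcriptId, intronIndex)
  L <- nchar(seq)
  from <- zone[1L]; to <- zone[2L]
  trunc <- FALSE
  if (from < -L) { from <- -L; trunc <- TRUE }
  if (to < from) return(structure("", truncated = TRUE))
  structure(substr(seq, L + from + 1L, L + to + 1L), truncated = trunc)
}

# cached transcribed-strand intron sequence
intronSequence <- function(db, transcriptId, intronIndex) {
  m <- S4Vectors::mcols(db@introns)
  i <- which(m$transcript_id == transcriptId & m$intron_index == intronIndex)
  if (!length(i)) stop(sprintf("unknown intron %s_IVS%s", transcriptId, intronIndex))
  m$seq[i[1L]]
}

#' Pyrimidine fraction of a sequence
#'
#' @param seq non-empty A/C/G/T character string.
#' @return (#C + #T) / length.
#' @export
pyrimidineContent <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("non-ACGT character(s): %s", paste(bad, collapse = ", ")))
  mean(ch %in% c("C", "T"))
}

#' Scan a sequence for (Y)AG dinucleotides
#'
#' Returns the 1-based position of the A of every AG occurrence; with
#' `requireYag` only occurrences immediately preceded by a pyrimidine are
#' kept (an AG at position 1 has no preceding base and is never a YAG).
#'
#' @param seq character string.
#' @param requireYag logical.
#' @return integer vector of A positions (1-based).
#' @export
scanNaturalAG <- function(seq, requireYag = FALSE) {
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) return(integer())
  hit <- which(ch[-n] == "A" & ch[-1L] == "G")
  if (requireYag)
    hit <- hit[hit > 1L & ch[pmax(hit - 1L, 1L)] %in% c("C", "T")]
  hit
}

#' Fraction of introns with an AG beyond BP+7
#'
#' The published depletion arithmetic: of the introns whose zone-1 sequence
#' contains an AG, most have it within 7 nt of the branchpoint; the product
#' `fracWithAg * (1 - fracWithin7)` is the fraction of introns carrying an AG
#' in the depleted [BP+8, ACC-4] range.
#'
#' @param fracWithAg,fracWithin7 fractions in [0, 1].
#' @return fraction in [0, 1].
#' @export
agDepletionStat <- function(fracWithAg, fracWithin7) {
  if (fracWithAg < 0 || fracWithAg > 1 || fracWithin7 < 0 || fracWithin7 > 1)
    stop("inputs must be fractions in [0, 1]")
  fracWithAg * (1 - fracWithin7)
}

#' Probability that a random sequence contains at least one AG
#'
#' Exact computation via the linear recurrence on the no-AG probability
#' t(k+1) = t(k) - pA*pG*t(k-1) (a 2-state transfer matrix on "last base is
#' A"), with i.i.d. base probabilities.
#'
#' @param n sequence length, >= 2.
#' @param baseProbs named probability vector over A/C/G/T (default uniform).
#' @return probability in [0, 1].
#' @export
probAtLeastOneAG <- function(n, baseProbs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n < 2L) stop("n must be >= 2")
  if (abs(sum(baseProbs) - 1) > 1e-9) stop("base probabilities must sum to 1")
  pAG <- unname(baseProbs["A"] * baseProbs["G"])
  tkm1 <- 1; tk <- 1  # t(0), t(1)
  for (k in seq_len(n - 1L)) {
    tkp1 <- tk - pAG * tkm1
    tkm1 <- tk; tk <- tkp1
  }
  1 - tk
}

# ---- RNA secondary structure -------------------------------------------------

#' Maximum base-pairing fold (Nussinov) in dot-bracket notation
#'
#' Bundled folding engine for concealment analysis: maximizes the number of
#' Watson-Crick plus GU wobble pairs with a minimum hairpin loop of 3
#' unpaired bases. DNA input is treated as its RNA transcript (T pairs as U).
#' An external MFE folder can be substituted wherever a dot-bracket string is
#' accepted.
#'
#' @param seq A/C/G/T(/U) character string.
#' @param minLoop minimum number of unpaired bases in a hairpin loop.
#' @return dot-bracket string of the same length.
#' @export
foldMaxPairing <- function(seq, minLoop = 3L) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ch[ch == "U"] <- "T"
  n <- length(ch)
  if (n == 0L) return("")
  canPair <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  M <- matrix(0L, n, n)
  if (n > minLoop + 1L) {
    for (d in (minLoop + 1L):(n - 1L)) {
      for (i in 1:(n - d)) {
        j <- i + d
        best <- M[i, j - 1L]  # j unpaired
        for (k in i:(j - minLoop - 1L)) {
          if (canPair(ch[k], ch[j])) {
            left <- if (k > i) M[i, k - 1L] else 0L
            inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
            cand <- left + inner + 1L
            if (cand > best) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i <= minLoop) next
    if (M[i, j] == M[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    done <- FALSE
    for (k in i:(j - minLoop - 1L)) {
      if (canPair(ch[k], ch[j])) {
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
        if (left + inner + 1L == M[i, j]) {
          db[k] <- "("; db[j] <- ")"
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          done <- TRUE
          break
        }
      }
    }
    if (!done) stack[[length(stack) + 1L]] <- c(i, j - 1L)
  }
  paste(db, collapse = "")
}

#' Is an AG concealed inside a stem?
#'
#' TRUE iff both the A and the G are base-paired (non-dot) with partners
#' inside the given sequence, per the supplied dot-bracket structure.
#'
#' @param seq sequence string.
#' @param dotBracket structure string of the same length, balanced.
#' @param agPos 1-based position of the A of an AG dinucleotide.
#' @return logical.
#' @export
agConcealment <- function(seq, dotBracket, agPos) {
  if (nchar(seq) != nchar(dotBracket))
    stop("sequence and structure lengths differ")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (agPos < 1L || agPos + 1L > length(ch) ||
      ch[agPos] != "A" || ch[agPos + 1L] != "G")
    stop(sprintf("position %d is not an AG", agPos))
  st <- strsplit(dotBracket, "", fixed = TRUE)[[1L]]
  partner <- rep(NA_integer_, length(st))
  stack <- integer()
  for (i in seq_along(st)) {
    if (st[i] == "(") stack <- c(stack, i)
    else if (st[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    } else if (st[i] != ".") stop(sprintf("invalid structure character '%s'", st[i]))
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  !is.na(partner[agPos]) && !is.na(partner[agPos + 1L])
}

#' Per-intron zone atlas
#'
#' One row per intron: branchpoint offsets, zone intervals and lengths,
#' pyrimidine fractions, natural AG/YAG positions (1-based within zone 1,
#' comma-separated) and the concealment flags of zone-1 AGs under the bundled
#' folder.
#'
#' @param db a [SpliceDb-class].
#' @param fold logical; compute structural concealment of zone-1 AGs
#'   (quadratic-time folding; disable for very large atlases).
#' @return data.frame.
#' @export
zoneAtlas <- function(db, fold = TRUE) {
  zt <- db@zoneTable
  out <- vector("list", nrow(zt))
  for (i in seq_len(nrow(zt))) {
    z <- zt[i, ]
    if (!is.na(z$skipped)) {
      out[[i]] <- cbind(z[c("transcript_id", "intron_index")],
        data.frame(bp1 = NA, bp2 = NA, zone1 = ".", zone2 = ".", zone3 = ".",
                   len1 = NA, len2 = NA, len3 = NA, y1 = NA, y2 = NA, y3 = NA,
                   ag_zone1 = ".", yag_zone1 = ".", concealed = ".",
                   skipped = z$skipped))
      next
    }
    fmt <- function(a, b) if (is.na(a)) "." else sprintf("[%d,%d]", a, b)
    s1 <- zoneSequence(db, z$transcript_id, z$intron_index, c(z$z1_from, z$z1_to))
    s2 <- zoneSequence(db, z$transcript_id, z$intron_index, c(z$z2_from, z$z2_to))
    s3 <- zoneSequence(db, z$transcript_id, z$intron_index, c(z$z3_from, z$z3_to))
    yfrac <- function(s) if (nzchar(s)) pyrimidineContent(s) else NA_real_
    ag1 <- if (nzchar(s1)) scanNaturalAG(s1) else integer()
    yag1 <- if (nzchar(s1)) scanNaturalAG(s1, requireYag = TRUE) else integer()
    conc <- "."
    if (fold && length(ag1)) {
      st <- foldMaxPairing(s1)
      conc <- paste(vapply(ag1, function(p) agConcealment(s1, st, p), logical(1)),
                    collapse = ",")
    }
    out[[i]] <- cbind(z[c("transcript_id", "intron_index")],
      data.frame(bp1 = z$bp1, bp2 = z$bp2,
        zone1 = fmt(z$z1_from, z$z1_to), zone2 = fmt(z$z2_from, z$z2_to),
        zone3 = fmt(z$z3_from, z$z3_to),
        len1 = nchar(s1), len2 = nchar(s2), len3 = nchar(s3),
        y1 = yfrac(s1), y2 = yfrac(s2), y3 = yfrac(s3),
        ag_zone1 = if (length(ag1)) paste(ag1, collapse = ",") else ".",
        yag_zone1 = if (length(yag1)) paste(yag1, collapse = ",") else ".",
        concealed = conc, skipped = NA_character_))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
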