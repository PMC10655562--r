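#' @include AllClasses.R
NULL

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", X = "Xaa", `*` = "*")

aa3 <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  paste(AA3[ch], collapse = "")
}

#' Minimal HGVS p. description of a protein change
#'
#' Produces the minimal protein-level description comparing a wild-type and
#' mutant sequence (both one-letter, stop not included): "p.(=)" for
#' identity, "p.0?" for transcript ablation, in-frame insertion
#' `p.X#_Y#insZZZ` (with trailing `*` when the insertion ends in a stop and
#' truncates the product), in-frame deletion `p.X#_Y#del` (delins when the
#' junctional residue changes identity), substitution `p.X#Y`, nonsense
#' `p.X#*`, and frameshift `p.X#Yfs*N` with N the stop position in the new
#' reading frame counting the first changed residue as 1.
#'
#' @param wt,mut one-letter protein strings.
#' @param frameshift logical; the mutant arose from a non-multiple-of-3
#'   length change.
#' @param stopInInsertion logical; an in-frame insertion carrying its own
#'   stop codon truncated the product.
#' @param ablation logical; the start codon was lost.
#' @return HGVS p. string.
#' @export
hgvsProtein <- function(wt, mut, frameshift = FALSE, stopInInsertion = FALSE,
                        ablation = FALSE) {
  if (ablation) return("p.0?")
  if (identical(wt, mut)) return("p.(=)")
  wch <- strsplit(wt, "", fixed = TRUE)[[1L]]
  mch <- strsplit(mut, "", fixed = TRUE)[[1L]]
  nw <- length(wch); nm <- length(mch)
  p <- 0L
  while (p < min(nw, nm) && wch[p + 1L] == mch[p + 1L]) p <- p + 1L

  if (frameshift) {
    # new stop sits at residue nm + 1 of the mutant; count from first change
    if (p >= nm)   # truncation directly at the changed residue
      return(sprintf("p.%s%d*", AA3[wch[p + 1L]], p + 1L))
    N <- nm + 1L - p
    if (N == 1L) return(sprintf("p.%s%d*", AA3[wch[p + 1L]], p + 1L))
    return(sprintf("p.%s%d%sfs*%d", AA3[wch[p + 1L]], p + 1L, AA3[mch[p + 1L]], N))
  }
  if (stopInInsertion) {
    extra <- if (nm > p) substr(mut, p + 1L, nm) else ""
    if (!nzchar(extra))  # immediate in-frame stop: nonsense at the next residue
      return(sprintf("p.%s%d*", AA3[wch[p + 1L]], p + 1L))
    return(sprintf("p.%s%d_%s%dins%s*", AA3[wch[p]], p, AA3[wch[p + 1L]],
                   p + 1L, aa3(extra)))
  }

  s <- 0L
  while (s < min(nw, nm) - p && wch[nw - s] == mch[nm - s]) s <- s + 1L
  wMid <- if (nw - s >= p + 1L) substr(wt, p + 1L, nw - s) else ""
  mMid <- if (nm - s >= p + 1L) substr(mut, p + 1L, nm - s) else ""
  lw <- nchar(wMid); lm <- nchar(mMid)
  if (lm == 0L) {                               # deletion
    if (lw == 1L) return(sprintf("p.%s%ddel", AA3[wch[p + 1L]], p + 1L))
    return(sprintf("p.%s%d_%s%ddel", AA3[wch[p + 1L]], p + 1L,
                   AA3[wch[p + lw]], p + lw))
  }
  if (lw == 0L) {                               # insertion
    if (p == 0L)   # N-terminal insertion: describe as extension-like delins
      return(sprintf("p.%s1delins%s", AA3[wch[1L]], aa3(paste0(mMid, wch[1L]))))
    return(sprintf("p.%s%d_%s%dins%s", AA3[wch[p]], p, AA3[wch[p + 1L]],
                   p + 1L, aa3(mMid)))
  }
  if (lw == 1L && lm == 1L)                     # substitution
    return(sprintf("p.%s%d%s", AA3[wch[p + 1L]], p + 1L, AA3[mch[p + 1L]]))
  if (lw == 1L)
    return(sprintf("p.%s%ddelins%s", AA3[wch[p + 1L]], p + 1L, aa3(mMid)))
  sprintf("p.%s%d_%s%ddelins%s", AA3[wch[p + 1L]], p + 1L,
          AA3[wch[p + lw]], p + lw, aa3(mMid))
}
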