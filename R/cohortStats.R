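#' @include AllClasses.R
NULL

#' Exact Fisher test for a 2x2 table
#'
#' Direct hypergeometric computation. The two-sided p-value follows the
#' point-probability convention of mainstream statistical software (sum of
#' tables whose probability does not exceed that of the observed table, with
#' a 1e-12 relative guard against floating ties); one-sided alternatives sum
#' the corresponding tail. The published YAG-enrichment p for the
#' 229/29/72/20 table (0.0122) is the "greater" (enrichment-direction)
#' value; the two-sided value for the same table is 0.0217.
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = groups,
#'   columns = outcome (table `rbind(c(a, b), c(c, d))`).
#' @param alternative "two.sided", "greater" or "less" (association of cell
#'   `a` relative to its margins).
#' @return p-value.
#' @export
fisherExact2x2 <- function(a, b, c, d,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  m <- a + b; n <- c + d; k1 <- a + c; k2 <- b + d
  if (m == 0 || n == 0 || k1 == 0 || k2 == 0)
    stop("all margins must be positive")
  lo <- max(0L, k1 - n); hi <- min(k1, m)
  x <- lo:hi
  px <- stats::dhyper(x, m, n, k1)
  pobs <- stats::dhyper(a, m, n, k1)
  switch(alternative,
    two.sided = sum(px[px <= pobs * (1 + 1e-12)]),
    greater   = sum(px[x >= a]),
    less      = sum(px[x <= a]))
}

#' Distance-window summary of a call set
#'
#' Shares of calls at least 8 nt from the branchpoint and at most 17 nt from
#' the acceptor (inclusive boundaries, as printed), with medians and full
#' histograms.
#'
#' @param calls data.frame with columns `AGAIN_BP_DIST` and `AGAIN_ACC_DIST`
#'   (or `bp_dist`/`acc_dist`).
#' @return list: shareBpGe8, shareAccLe17, medianBpDist, medianAccDist,
#'   bpHist, accHist.
#' @export
distanceSummary <- function(calls) {
  bp <- calls[["AGAIN_BP_DIST"]]; if (is.null(bp)) bp <- calls[["bp_dist"]]
  ac <- calls[["AGAIN_ACC_DIST"]]; if (is.null(ac)) ac <- calls[["acc_dist"]]
  if (is.null(bp) || is.null(ac) || !length(bp)) stop("empty or invalid call set")
  list(shareBpGe8 = mean(bp >= 8L), shareAccLe17 = mean(ac <= 17L),
       medianBpDist = stats::median(bp), medianAccDist = stats::median(ac),
       bpHist = table(bp), accHist = table(ac))
}

#' Allele-frequency category of a variant
#'
#' Singleton (AC = 1) takes precedence; otherwise common iff MAF >= 1%
#' (boundary inclusive), else rare.
#'
#' @param ac allele count, 0 < ac <= an.
#' @param an allele number.
#' @return "singleton", "rare" or "common".
#' @export
mafCategorize <- function(ac, an) {
  if (ac <= 0 || ac > an) stop("require 0 < ac <= an")
  if (ac == 1) return("singleton")
  if (ac / an >= 0.01) "common" else "rare"
}

#' Cohort-level summary of a scan table
#'
#' Counts by zone and mechanism, distance-window shares, the score histogram
#' and, when AC/AN columns are supplied, allele-frequency categories.
#'
#' @param tab scan table from [scanVariants()].
#' @param ac,an optional allele count/number vectors aligned with `tab` rows.
#' @return list of summaries.
#' @export
cohortSummary <- function(tab, ac = NULL, an = NULL) {
  out <- list(n = nrow(tab),
              byZone = table(tab$AGAIN_ZONE),
              scoreHist = table(factor(tab$AGAIN_SCORE, levels = 1:5)))
  if ("MECHANISM" %in% names(tab)) out$byMechanism <- table(tab$MECHANISM)
  if (nrow(tab)) out <- c(out, distanceSummary(tab))
  if (!is.null(ac) && !is.null(an)) {
    cats <- mapply(mafCategorize, ac, an)
    out$mafCategories <- table(factor(cats, levels = c("singleton", "rare", "common")))
  }
  out
}
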