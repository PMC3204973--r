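# Pairwise-site linkage-disequilibrium scan.

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table.  Thin
#' wrapper over [stats::fisher.test()]; an all-zero table is not testable and
#' returns `NA`.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts.
#' @return two-sided p-value, or `NA_real_` for an all-zero table.
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisherExact2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (sum(table) == 0) return(NA_real_)
  stats::fisher.test(table)$p.value
}

#' LD ratio from significant and total pair counts
#'
#' `100 * Ps / PT`, the percentage of pairwise comparisons significant after
#' Bonferroni correction; `NA` (not 0) when no pairs are testable.
#'
#' @param ps number of significant pairs.
#' @param pt number of testable pairs.
#' @return percentage in `[0, 100]`, or `NA_real_` when `pt == 0`.
#' @export
ldRatio <- function(ps, pt) {
  stopifnot(ps >= 0, pt >= 0, ps <= pt | pt == 0)
  if (pt == 0) return(NA_real_)
  100 * ps / pt
}

# parsimony-informative columns of a retained matrix: at least two alleles
# each carried by at least two sequences
.informativeColumns <- function(m) {
  if (ncol(m) == 0L) return(integer())
  cnt <- .alleleCounts(m)
  which(colSums(cnt >= 2L) >= 2L)
}

#' Pairwise-site LD scan of one marker
#'
#' Tests association between all pairs of parsimony-informative sites (sites
#' with at least two alleles each present in at least two sequences, after
#' complete deletion).  Each pair is reduced to a 2 x 2 table of phased
#' haplotype counts by scoring each site as major allele versus pooled minor
#' alleles (ties broken toward the alphabetically first base), and tested
#' with Fisher's exact test.  A pair is significant when
#' `p < alpha / P_T` (per-marker Bonferroni; the marker-cohort scan is its
#' own test family).
#'
#' @param alignment a [LocusAlignment-class] (one cohort's haplotypes).
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `LDResult`: `marker`, `Ps`, `PT`, `ratio`
#'   (percentage, `NA` when `PT == 0`), `alphaEffective`, and
#'   `informativeSites` (retained-column indices).
#' @export
ldScan <- function(alignment, alpha = 0.05) {
  m <- .retainedMatrix(alignment)
  info <- .informativeColumns(m)
  PT <- choose(length(info), 2)
  out <- list(marker = marker(alignment), Ps = 0L, PT = as.integer(PT),
              ratio = NA_real_, alphaEffective = NA_real_,
              informativeSites = info)
  class(out) <- "LDResult"
  if (PT == 0) return(out)
  alphaEff <- alpha / PT
  # binary major/minor score per informative site
  sub <- m[, info, drop = FALSE]
  cnt <- .alleleCounts(sub)
  majorIdx <- apply(cnt, 2L, which.max)   # ties -> first (alphabetical) base
  isMajor <- sub == matrix(BASES[majorIdx], nrow(sub), ncol(sub), byrow = TRUE)
  ps <- 0L
  nI <- length(info)
  for (i in seq_len(nI - 1L)) {
    xi <- isMajor[, i]
    for (j in seq.int(i + 1L, nI)) {
      xj <- isMajor[, j]
      tab <- matrix(c(sum(xi & xj), sum(xi & !xj),
                      sum(!xi & xj), sum(!xi & !xj)), 2L)
      p <- fisherExact2x2(tab)
      if (!is.na(p) && p < alphaEff) ps <- ps + 1L
    }
  }
  out$Ps <- ps
  out$ratio <- ldRatio(ps, PT)
  out$alphaEffective <- alphaEff
  out
}

#' @export
print.LDResult <- function(x, ...) {
  cat(sprintf("LDResult '%s': Ps=%d, PT=%d, ratio=%s%%\n", x$marker, x$Ps,
              x$PT, if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio)))
  invisible(x)
}
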