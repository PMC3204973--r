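# Per-SNP allele-frequency comparison between cohorts and the
# low-frequency allele-loss statistic.

#' Per-SNP allele-frequency table with chi-square tests
#'
#' For every marker, builds per-cohort allele counts at each indel-free site
#' that is polymorphic in the pooled sample, and tests the allele-count
#' contingency table (alleles x cohorts; 2 x 2 for biallelic sites) with a
#' chi-square test without continuity correction.  Sites monomorphic in both
#' cohorts and columns containing `-` or `N` are excluded.  A site is skipped
#' and flagged (`tested = FALSE`) when one cohort contributes no sequences.
#'
#' @param dataset a [MultiLocusDataset-class].
#' @param alpha per-SNP significance level (default 0.05; no multiple-testing
#'   correction, by design -- the summary of interest is the raw significant
#'   fraction).
#' @param fisherFallback when TRUE, sites with any expected count below 5 are
#'   tested with Fisher's exact test instead; off by default (the chi-square
#'   convention).
#' @return data.frame with one row per (marker, site, allele): cohort counts
#'   and frequencies, plus per-site `chi2`, `p`, `significant`, `tested`.
#'   Site indices refer to retained (complete-deletion) columns of the pooled
#'   alignment.
#' @export
snpTable <- function(dataset, alpha = 0.05, fisherFallback = FALSE) {
  rows <- list()
  for (m in names(alignments(dataset))) {
    aln <- alignments(dataset)[[m]]
    wild <- cohortSlice(aln, samples(dataset), "wild")
    dom <- cohortSlice(aln, samples(dataset), "domestic")
    pooled <- methods::new("LocusAlignment", marker = m,
                           seqs = c(sequences(wild), sequences(dom)))
    mat <- .retainedMatrix(pooled)
    if (ncol(mat) == 0L) next
    nW <- nSequences(wild)
    iW <- seq_len(nW)
    iD <- seq.int(nW + 1L, nrow(mat))
    cntW <- .alleleCounts(mat[iW, , drop = FALSE])
    cntD <- .alleleCounts(mat[iD, , drop = FALSE])
    cntAll <- cntW + cntD
    poly <- which(colSums(cntAll > 0L) >= 2L)
    for (s in poly) {
      alleles <- BASES[cntAll[, s] > 0L]
      tab <- rbind(wild = cntW[alleles, s], domestic = cntD[alleles, s])
      tested <- nW >= 1L && length(iD) >= 1L &&
        sum(tab["wild", ]) > 0L && sum(tab["domestic", ]) > 0L
      chi2 <- p <- NA_real_
      if (tested) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
        if (fisherFallback && any(ct$expected < 5))
          p <- stats::fisher.test(t(tab))$p.value
      }
      fW <- cntW[alleles, s] / max(1L, sum(cntW[alleles, s]))
      fD <- cntD[alleles, s] / max(1L, sum(cntD[alleles, s]))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, site = s, allele = alleles,
        count_wild = unname(cntW[alleles, s]),
        count_domestic = unname(cntD[alleles, s]),
        freq_wild = unname(fW), freq_domestic = unname(fD),
        chi2 = chi2, p = p,
        significant = tested & !is.na(p) & p < alpha, tested = tested)
    }
  }
  if (!length(rows))
    return(data.frame(marker = character(), site = integer(),
                      allele = character(), count_wild = integer(),
                      count_domestic = integer(), freq_wild = numeric(),
                      freq_domestic = numeric(), chi2 = numeric(),
                      p = numeric(), significant = logical(),
                      tested = logical()))
  do.call(rbind, rows)
}

#' Fraction of SNPs with significantly different allele frequencies
#'
#' @param snp a table from [snpTable()], or the testable SNP count.
#' @param nSignificant when `snp` is a count: number of significant SNPs.
#' @return percentage of tested SNP sites significant at the table's alpha.
#' @export
significantSnpPercent <- function(snp, nSignificant = NULL) {
  if (is.data.frame(snp)) {
    perSite <- unique(snp[snp$tested, c("marker", "site", "significant")])
    key <- paste(perSite$marker, perSite$site)
    sig <- tapply(perSite$significant, key, any)
    return(100 * mean(sig))
  }
  stopifnot(!is.null(nSignificant), snp > 0)
  100 * nSignificant / snp
}

#' Loss of low-frequency alleles in the domestic cohort
#'
#' Counts the `(marker, site, allele)` combinations whose frequency in the
#' wild cohort is strictly positive and strictly below `threshold`, and how
#' many of those alleles are still present (observed at least once, at any
#' frequency) in the domestic cohort.  The loss percentage is
#' `100 * (nWildLow - nRetained) / nWildLow`.
#'
#' @param snp a table from [snpTable()] (or a [MultiLocusDataset-class],
#'   which is tabulated first).
#' @param threshold wild-cohort frequency cutoff (default 0.10; the
#'   alternative 0.05 convention can be selected here).
#' @return list with `nWildLow`, `nRetained`, `lossPercent` (`NA` when no
#'   wild low-frequency alleles exist).
#' @export
lowFreqLoss <- function(snp, threshold = 0.10) {
  if (is(snp, "MultiLocusDataset")) snp <- snpTable(snp)
  low <- snp$freq_wild > 0 & snp$freq_wild < threshold
  nLow <- sum(low)
  nKept <- sum(low & snp$count_domestic >= 1L)
  list(nWildLow = nLow, nRetained = nKept,
       lossPercent = lowFreqLossPercent(nLow, nKept))
}

#' @rdname lowFreqLoss
#' @param nWildLow number of low-frequency alleles in the wild cohort.
#' @param nRetained number of those still observed in the domestic cohort.
#' @export
lowFreqLossPercent <- function(nWildLow, nRetained) {
  stopifnot(nRetained <= nWildLow)
  if (nWildLow == 0) return(NA_real_)
  100 * (nWildLow - nRetained) / nWildLow
}
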