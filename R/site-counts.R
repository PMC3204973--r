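# Internal alignment-matrix machinery shared by the statistics modules.
#
# Deletion policy ("complete deletion"): any column containing '-' or 'N' in
# any sequence is dropped before anything is counted, so every statistic of a
# sample shares one effective length.

.alnMatrix <- function(x) {
  if (is(x, "LocusAlignment")) x <- x@seqs
  m <- as.matrix(x)
  storage.mode(m) <- "character"
  m
}

# columns free of gaps and missing data
.retainedMatrix <- function(m) {
  if (is(m, "LocusAlignment")) m <- .alnMatrix(m)
  if (ncol(m) == 0L) return(m)
  ok <- colSums(m == "-" | m == "N") == 0L
  m[, ok, drop = FALSE]
}

BASES <- c("A", "C", "G", "T")

# 4 x L matrix of allele counts per retained column
.alleleCounts <- function(m) {
  out <- vapply(BASES, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, BASES))
  t(out)  # 4 x L
}

#' Segregating-site counts of an alignment
#'
#' Applies complete deletion (every column containing `-` or `N` is excluded)
#' and then counts: `S`, the number of segregating (polymorphic) columns;
#' `eta`, the minimum number of mutations (alleles minus one, summed over
#' columns, so a triallelic column adds 2); `eta_s`, the number of singleton
#' mutations (alleles observed in exactly one sequence); and `k`, the mean
#' number of pairwise differences over all `choose(n, 2)` sequence pairs on
#' the retained columns.  `k` and `S` are per-locus quantities; division by
#' `L_effective` is left to the per-site statistics.
#'
#' @param alignment a [LocusAlignment-class] (or a character matrix of
#'   sequences in rows).
#' @return a list of class `SiteCounts` with elements `n`, `S`, `eta`,
#'   `eta_s`, `k`, `L_effective`.
#' @examples
#' a <- LocusAlignment("toy", c(h1 = "AAAA", h2 = "AAAT", h3 = "ACAA", h4 = "AAAA"))
#' siteCounts(a)
#' @export
siteCounts <- function(alignment) {
  m <- .retainedMatrix(alignment)
  n <- nrow(m)
  if (n < 2L)
    stop("insufficient-data error: need at least 2 sequences, got ", n)
  L <- ncol(m)
  if (L == 0L) {
    out <- list(n = n, S = 0L, eta = 0L, eta_s = 0L, k = 0, L_effective = 0L)
    class(out) <- "SiteCounts"
    return(out)
  }
  cnt <- .alleleCounts(m)                      # 4 x L
  nAlleles <- colSums(cnt > 0L)
  poly <- nAlleles >= 2L
  S <- sum(poly)
  eta <- sum(nAlleles[poly] - 1L)
  eta_s <- if (S) sum(cnt[, poly, drop = FALSE] == 1L) else 0L
  npairs <- choose(n, 2)
  same <- colSums(choose(cnt, 2))              # monomorphic pairs per column
  k <- sum((npairs - same) / npairs)
  out <- list(n = n, S = as.integer(S), eta = as.integer(eta),
              eta_s = as.integer(eta_s), k = k, L_effective = as.integer(L))
  class(out) <- "SiteCounts"
  out
}

#' @export
print.SiteCounts <- function(x, ...) {
  cat(sprintf("SiteCounts: n=%d, S=%d, eta=%d, eta_s=%d, k=%.4f, L_eff=%d\n",
              x$n, x$S, x$eta, x$eta_s, x$k, x$L_effective))
  invisible(x)
}

.asSiteCounts <- function(x) {
  if (inherits(x, "SiteCounts")) x else siteCounts(x)
}

# harmonic sums
.a1 <- function(n) sum(1 / seq_len(n - 1L))
.a2 <- function(n) sum(1 / seq_len(n - 1L)^2)
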