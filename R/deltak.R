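# Post-processing of clustering log-likelihood tables: mean LnP(X|K) and
# the Evanno second-order statistic used to choose the number of clusters.

#' Evanno's delta-K from a clustering likelihood table
#'
#' Given replicate-run log-likelihoods `LnP(X|K)` for consecutive values of
#' `K`, computes the per-K mean and sample standard deviation and the Evanno
#' statistic `deltaK(K) = mean over runs |L(K+1) - 2 L(K) + L(K-1)| / SD(L(K))`,
#' where the second difference is taken within each run and the SD across
#' runs.  Delta-K is undefined at the endpoint K values and wherever the
#' run-to-run SD is zero (returned as `NA`, flagged by a warning, never a
#' division error).
#'
#' @param table data.frame with columns `K`, `run`, `lnP` -- at least three
#'   consecutive K values and at least two runs per K, with matching run ids
#'   across K.
#' @return data.frame with per-K `meanLnP`, `sdLnP`, `deltaK`.
#' @examples
#' tab <- expand.grid(K = 1:3, run = 1:3)
#' tab$lnP <- c(-101, -91, -90, -100, -90, -89, -99, -89, -88)
#' evannoDeltaK(tab)
#' @export
evannoDeltaK <- function(table) {
  stopifnot(all(c("K", "run", "lnP") %in% names(table)))
  Ks <- sort(unique(table$K))
  if (length(Ks) < 3L)
    stop("need at least 3 consecutive K values for delta-K")
  if (any(diff(Ks) != 1L))
    stop("K values must be consecutive integers")
  runs <- sort(unique(table$run))
  if (length(runs) < 2L)
    stop("need at least 2 runs per K to form the run-to-run SD")
  L <- matrix(NA_real_, length(runs), length(Ks),
              dimnames = list(as.character(runs), as.character(Ks)))
  L[cbind(match(table$run, runs), match(table$K, Ks))] <- table$lnP
  if (anyNA(L))
    stop("every run must report lnP at every K (incomplete table)")
  meanL <- colMeans(L)
  sdL <- apply(L, 2L, sd)
  dK <- rep(NA_real_, length(Ks))
  for (j in seq_along(Ks)[-c(1L, length(Ks))]) {
    if (sdL[j] == 0) {
      warning("run-to-run SD is zero at K = ", Ks[j], "; delta-K undefined there")
      next
    }
    dK[j] <- mean(abs(L[, j + 1L] - 2 * L[, j] + L[, j - 1L])) / sdL[j]
  }
  data.frame(K = Ks, meanLnP = unname(meanL), sdLnP = unname(sdL), deltaK = dK)
}

#' Read a clustering likelihood table from TSV
#'
#' @param path TSV with columns `K`, `run`, `lnP`.
#' @return the data.frame, numerically typed.
#' @export
readDeltaKTable <- function(path) {
  tb <- read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("K", "run", "lnP") %in% names(tb)))
  tb$K <- as.integer(tb$K); tb$lnP <- as.numeric(tb$lnP)
  tb
}
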