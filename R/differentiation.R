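# Between-cohort and hierarchical differentiation.

# per-site allele counts for a subset of rows
.meanPairwiseWithin <- function(cnt, n) {
  if (n < 2L) return(NA_real_)
  npairs <- choose(n, 2)
  sum((npairs - colSums(choose(cnt, 2))) / npairs)
}

#' Hudson's F_ST between two cohorts
#'
#' The sequence-based estimator `F_ST = 1 - H_w / H_b`, where `H_w` is the
#' unweighted mean of the two within-cohort mean pairwise difference counts
#' and `H_b` the mean pairwise difference count between cohorts, all on the
#' retained (complete-deletion) columns of the pooled alignment.  Negative
#' estimates are reported as computed, never clamped.  When `H_b = 0` (no
#' between-cohort variation) the statistic is undefined and `NA` is returned.
#'
#' @param alignment a [LocusAlignment-class] containing both cohorts'
#'   sequences.
#' @param cohortOf character/factor of length `nSequences(alignment)` giving
#'   each sequence's cohort (exactly two distinct values).
#' @return F_ST (numeric scalar, possibly negative), or `NA_real_`.
#' @export
hudsonFst <- function(alignment, cohortOf) {
  m <- .retainedMatrix(alignment)
  cohortOf <- as.character(cohortOf)
  stopifnot(length(cohortOf) == nrow(m))
  lv <- sort(unique(cohortOf))
  if (length(lv) != 2L)
    stop("hudsonFst needs exactly two cohorts, got ", length(lv))
  i1 <- cohortOf == lv[1L]; i2 <- cohortOf == lv[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop("insufficient-data error: each cohort needs >= 2 sequences")
  if (ncol(m) == 0L) return(NA_real_)
  c1 <- .alleleCounts(m[i1, , drop = FALSE])
  c2 <- .alleleCounts(m[i2, , drop = FALSE])
  hw <- (.meanPairwiseWithin(c1, n1) + .meanPairwiseWithin(c2, n2)) / 2
  # mean between-cohort differences: 1 - sum_a p1a p2a, per column
  hb <- sum(1 - colSums((c1 / n1) * (c2 / n2)))
  if (hb == 0) return(NA_real_)
  1 - hw / hb
}

# Hierarchical sums of squared deviations from a squared-distance matrix.
# d2 is symmetric with zero diagonal; pop and grp are per-sequence labels.
# Returns SSD at the three strata plus the moment coefficients.
.amovaDecompose <- function(d2, grp, pop) {
  N <- nrow(d2)
  ssdTotal <- sum(d2) / (2 * N)
  popKey <- paste(grp, pop, sep = "\r")
  # block sums per population and per group
  blockSum <- function(lab) {
    r <- rowsum(d2, lab)
    m <- rowsum(t(r), lab)
    diag(m)
  }
  nPop <- table(popKey)
  nGrp <- table(grp)
  bp <- blockSum(popKey)
  ssdWithinPop <- sum(bp / (2 * as.numeric(nPop[names(bp)])))
  bg <- blockSum(grp)
  ssdWithinGrp <- sum(bg / (2 * as.numeric(nGrp[names(bg)])))
  ssdAP <- ssdWithinGrp - ssdWithinPop
  ssdAG <- ssdTotal - ssdWithinGrp
  G <- length(nGrp); P <- length(nPop)
  # expected-mean-square coefficients (unbalanced design)
  popSizes <- as.numeric(nPop)
  popGrp <- vapply(strsplit(names(nPop), "\r", fixed = TRUE), `[`, "", 1L)
  sumSqByGrp <- vapply(names(nGrp), function(g)
    sum(popSizes[popGrp == g]^2) / as.numeric(nGrp[g]), numeric(1))
  nC1 <- (N - sum(sumSqByGrp)) / (P - G)                       # n'
  nC2 <- (sum(sumSqByGrp) - sum(popSizes^2) / N) / (G - 1)     # n''
  nC3 <- (N - sum(as.numeric(nGrp)^2) / N) / (G - 1)           # n'''
  list(ssd = c(among_groups = ssdAG, among_pops = ssdAP, within_pops = ssdWithinPop),
       df = c(G - 1, P - G, N - P), n = c(nC1, nC2, nC3),
       G = G, P = P, N = N)
}

.amovaComponents <- function(dec) {
  df <- dec$df; ssd <- dec$ssd
  msWP <- if (df[3L] > 0) ssd[[3L]] / df[3L] else NA_real_
  sigC <- msWP
  sigB <- if (df[2L] > 0) (ssd[[2L]] / df[2L] - sigC) / dec$n[1L] else NA_real_
  sigA <- if (df[1L] > 0) {
    msAG <- ssd[[1L]] / df[1L]
    (msAG - sigC - dec$n[2L] * (if (is.na(sigB)) 0 else sigB)) / dec$n[3L]
  } else NA_real_
  c(sigma2_among_groups = unname(sigA),
    sigma2_among_pops_within_groups = unname(sigB),
    sigma2_within_pops = unname(sigC))
}

.phiFromComponents <- function(comp, scUndefined = FALSE) {
  sigA <- comp[[1L]]; sigB <- comp[[2L]]; sigC <- comp[[3L]]
  # a stratum that does not exist (one population per group) contributes
  # nothing to the total rather than poisoning it
  sigB0 <- if (is.na(sigB)) 0 else sigB
  tot <- sigA + sigB0 + sigC
  phiCT <- if (!is.na(tot) && tot != 0) sigA / tot else NA_real_
  phiSC <- if (!scUndefined && !is.na(sigB) && (sigB + sigC) != 0)
    sigB / (sigB + sigC) else NA_real_
  phiST <- if (!is.na(tot) && tot != 0) (sigA + sigB0) / tot else NA_real_
  c(phi_CT = phiCT, phi_SC = phiSC, phi_ST = phiST)
}

#' Hierarchical AMOVA with permutation tests
#'
#' Analysis of molecular variance: method-of-moments partitioning of the
#' squared molecular distances (here the raw pairwise difference counts on
#' retained columns, the conventional choice for sequence data) into
#' variance among groups, among populations within groups, and within
#' populations, with the fixation indices `Phi_CT = sigma2_a / sigma2_total`,
#' `Phi_SC = sigma2_b / (sigma2_b + sigma2_c)` and
#' `Phi_ST = (sigma2_a + sigma2_b) / sigma2_total`.
#'
#' Permutation null distributions follow the standard scheme: whole
#' populations are permuted among groups for `Phi_CT`; sequences among all
#' populations for `Phi_ST`; sequences among populations within their group
#' for `Phi_SC`.  P-values use the add-one correction
#' `(#\{perm >= obs\} + 1) / (nPerm + 1)`.
#'
#' @param alignment a [LocusAlignment-class] (or a precomputed symmetric
#'   matrix of squared distances).
#' @param partition data.frame with per-sequence columns `group` and
#'   `population`, rows in alignment order.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return an [AmovaResult-class].  With a single population per group
#'   throughout, `Phi_SC` is reported `NA`; with no molecular variation all
#'   Phi are `NA`.
#' @export
amova <- function(alignment, partition, nPerm = 1000L, seed = 1L) {
  if (is.matrix(alignment) && is.numeric(alignment)) {
    d2 <- alignment
  } else {
    m <- .retainedMatrix(alignment)
    d2 <- .pairwiseDiffMatrix(m)
  }
  N <- nrow(d2)
  stopifnot(nrow(partition) == N)
  grp <- as.character(partition$group)
  pop <- as.character(partition$population)
  if (length(unique(paste(grp, pop))) < 2L)
    stop("amova needs at least 2 populations")
  dec <- .amovaDecompose(d2, grp, pop)
  comp <- .amovaComponents(dec)
  scUndef <- dec$P == dec$G
  phi <- .phiFromComponents(comp, scUndef)
  allZero <- sum(dec$ssd) == 0
  if (allZero) phi[] <- NA_real_
  p <- c(phi_CT = NA_real_, phi_SC = NA_real_, phi_ST = NA_real_)
  if (nPerm > 0L && !allZero) {
    set.seed(seed)
    obs <- phi
    popKey <- paste(grp, pop, sep = "\r")
    pops <- unique(popKey)
    popGrp <- grp[match(pops, popKey)]
    hits <- c(phi_CT = 0L, phi_SC = 0L, phi_ST = 0L)
    for (b in seq_len(nPerm)) {
      if (!is.na(obs["phi_ST"])) {
        # permute sequences among populations (group labels follow populations)
        perm <- sample(N)
        ph <- .phiFromComponents(.amovaComponents(
          .amovaDecompose(d2, grp[perm], popKey[perm])), scUndef)
        if (!is.na(ph["phi_ST"]) && ph["phi_ST"] >= obs["phi_ST"])
          hits["phi_ST"] <- hits["phi_ST"] + 1L
      }
      if (!is.na(obs["phi_CT"])) {
        permGrp <- sample(popGrp)
        newGrp <- permGrp[match(popKey, pops)]
        ph <- .phiFromComponents(.amovaComponents(
          .amovaDecompose(d2, newGrp, pop)), scUndef)
        if (!is.na(ph["phi_CT"]) && ph["phi_CT"] >= obs["phi_CT"])
          hits["phi_CT"] <- hits["phi_CT"] + 1L
      }
      if (!is.na(obs["phi_SC"])) {
        permWithin <- seq_len(N)
        for (g in unique(grp)) {
          ix <- which(grp == g)
          permWithin[ix] <- ix[sample.int(length(ix))]
        }
        ph <- .phiFromComponents(.amovaComponents(
          .amovaDecompose(d2, grp, pop[permWithin])), scUndef)
        if (!is.na(ph["phi_SC"]) && ph["phi_SC"] >= obs["phi_SC"])
          hits["phi_SC"] <- hits["phi_SC"] + 1L
      }
    }
    for (nm in names(p))
      if (!is.na(obs[nm])) p[nm] <- (hits[nm] + 1L) / (nPerm + 1L)
  }
  methods::new("AmovaResult", components = comp, phi = phi, pValues = p,
               nPermutations = as.numeric(nPerm),
               ssd = unname(dec$ssd), df = unname(dec$df))
}

# pairwise difference counts (used as squared distances) between all rows
.pairwiseDiffMatrix <- function(m) {
  n <- nrow(m)
  if (ncol(m) == 0L) return(matrix(0, n, n))
  num <- matrix(0L, n, ncol(m))
  for (b in seq_along(BASES)) num[m == BASES[b]] <- b
  d <- matrix(0, n, n)
  # column-block accumulation keeps memory modest for long loci
  for (b in seq_along(BASES)) {
    ind <- num == b
    d <- d + tcrossprod(ind)
  }
  L <- ncol(m)
  L - d
}
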