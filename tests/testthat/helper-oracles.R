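# Independent oracle implementations used to cross-check the package's
# statistics.  These are deliberately written from the published formulas in
# a different shape than the package code (explicit loops, no shared
# helpers) so that agreement is evidence, not tautology.

# Tajima (1989) constants and statistic, written out longhand.
oracleTajimasD <- function(n, S, k) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) starred statistics with the corrected variance terms
# (Simonsen, Churchill & Aquadro 1995), transcribed independently.
oracleFuLi <- function(n, eta, etaS, k) {
  a <- sum(1 / seq_len(n - 1))
  b <- sum(1 / seq_len(n - 1)^2)
  aPlus <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * aPlus - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn - 2 * (n * a * (a + 1)) / (n - 1)^2) /
    (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - a * etaS) / sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (aPlus - 2 * n / (n + 1))) / a - vF
  Fstar <- (k - ((n - 1) / n) * etaS) / sqrt(uF * eta + vF * eta^2)
  c(Dstar = Dstar, Fstar = Fstar)
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracleFisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(NA_real_)
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Brute-force mean pairwise difference counts among/between sets of strings.
oracleMeanPairwise <- function(strs1, strs2 = NULL) {
  diffs <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  if (is.null(strs2)) {
    n <- length(strs1); tot <- 0; cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tot <- tot + diffs(strs1[i], strs1[j]); cnt <- cnt + 1
    }
    return(tot / cnt)
  }
  tot <- 0
  for (x in strs1) for (y in strs2) tot <- tot + diffs(x, y)
  tot / (length(strs1) * length(strs2))
}

# Hand-solved AMOVA for a BALANCED design: G groups, P0 pops per group,
# n0 sequences per pop.  With balance the moment coefficients reduce to
# n' = n0, n'' = n0 * P0, n''' = n0 * P0 (standard nested ANOVA), and the
# SSDs follow directly from block sums of the squared-distance matrix.
oracleAmovaBalanced <- function(d2, grp, pop) {
  N <- nrow(d2)
  popKey <- paste(grp, pop)
  pops <- unique(popKey); grps <- unique(grp)
  n0 <- N / length(pops); P0 <- length(pops) / length(grps)
  ssdT <- sum(d2) / (2 * N)
  ssdWP <- 0
  for (p in pops) {
    ix <- which(popKey == p)
    ssdWP <- ssdWP + sum(d2[ix, ix]) / (2 * length(ix))
  }
  ssdWG <- 0
  for (g in grps) {
    ix <- which(grp == g)
    ssdWG <- ssdWG + sum(d2[ix, ix]) / (2 * length(ix))
  }
  dfAG <- length(grps) - 1
  dfAP <- length(pops) - length(grps)
  dfWP <- N - length(pops)
  msAG <- (ssdT - ssdWG) / dfAG
  msAP <- (ssdWG - ssdWP) / dfAP
  msWP <- ssdWP / dfWP
  sigC <- msWP
  sigB <- (msAP - sigC) / n0
  sigA <- (msAG - sigC - n0 * sigB) / (n0 * P0)
  c(sigA = sigA, sigB = sigB, sigC = sigC)
}
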