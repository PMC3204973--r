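# Per-cohort, per-marker diversity and neutrality statistics.

#' Nucleotide diversity per site
#'
#' The average number of nucleotide differences per site between two randomly
#' chosen sequences: `pi = k / L_effective`, with `k` the mean pairwise
#' difference count on the retained (complete-deletion) columns.
#'
#' @param x a [LocusAlignment-class] or a `SiteCounts` list from
#'   [siteCounts()].
#' @return per-site diversity (numeric scalar).
#' @export
nucleotideDiversity <- function(x) {
  counts <- .asSiteCounts(x)
  if (counts$L_effective < 1L)
    stop("undefined-statistic error: no retained sites (L_effective = 0)")
  counts$k / counts$L_effective
}

#' Watterson's theta per site, with a site-bootstrap interval
#'
#' `theta_W = S / (a1 * L_effective)` with `a1 = sum(1/i, i = 1..n-1)`.  The
#' optional confidence interval resamples retained alignment columns with
#' replacement and takes the 2.5/97.5 percentiles of the recomputed
#' estimates.  This interval quantifies sampling noise across sites; it is a
#' bootstrap interval, not a Bayesian credible interval.
#'
#' @param x a [LocusAlignment-class]; a bare `SiteCounts` object is accepted
#'   when `nBoot = 0`.
#' @param nBoot number of bootstrap resamples (0 skips the interval).
#' @param seed integer seed for the bootstrap.
#' @return list with `theta` and `ci` (`c(low, high)`, `NA` when not
#'   bootstrapped).
#' @export
wattersonTheta <- function(x, nBoot = 0L, seed = 1L) {
  counts <- .asSiteCounts(x)
  if (counts$n < 2L) stop("insufficient-data error: need n >= 2")
  if (counts$L_effective < 1L)
    stop("undefined-statistic error: no retained sites (L_effective = 0)")
  a1 <- .a1(counts$n)
  theta <- counts$S / (a1 * counts$L_effective)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    if (!is(x, "LocusAlignment") && !is.matrix(x))
      stop("bootstrap interval needs the alignment, not bare SiteCounts")
    m <- .retainedMatrix(x)
    L <- ncol(m)
    cnt <- .alleleCounts(m)
    poly <- colSums(cnt > 0L) >= 2L        # per-column segregating indicator
    set.seed(seed)
    boot <- vapply(seq_len(nBoot), function(i) {
      sum(poly[sample.int(L, L, replace = TRUE)]) / (a1 * L)
    }, numeric(1))
    ci <- unname(quantile(boot, c(0.025, 0.975)))
  }
  list(theta = theta, ci = ci)
}

.tajimaConstants <- function(n) {
  a1 <- .a1(n); a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standardized difference between the pairwise-difference and
#' segregating-sites estimators of theta:
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with the usual constants in
#' n.  Negative D indicates an excess of rare variants.  When `S = 0` the
#' statistic is undefined and `NA` is returned (never 0).
#'
#' @param x a [LocusAlignment-class] or `SiteCounts`.
#' @return Tajima's D, or `NA_real_` when `S = 0`.
#' @export
tajimasD <- function(x) {
  counts <- .asSiteCounts(x)
  n <- counts$n; S <- counts$S
  if (n < 2L) stop("insufficient-data error: need n >= 2")
  if (S == 0L) return(NA_real_)
  cc <- .tajimaConstants(n)
  (counts$k - S / cc$a1) / sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' The starred neutrality statistics contrast singleton mutations (`eta_s`)
#' with the total mutation count (`eta`, for D*) or the mean pairwise
#' difference (`k`, for F*).  Variances use the corrected expressions of
#' Simonsen, Churchill & Aquadro (1995), the convention adopted by standard
#' software.  An excess of singletons drives both statistics negative.  When
#' `eta = 0` both are undefined and returned as `NA`.
#'
#' @param x a [LocusAlignment-class] or `SiteCounts`.
#' @return named numeric `c(D_star = , F_star = )`.
#' @export
fuLiStars <- function(x) {
  counts <- .asSiteCounts(x)
  n <- counts$n
  if (n < 3L) stop("insufficient-data error: need n >= 3 for D*/F*")
  eta <- counts$eta; eta_s <- counts$eta_s; k <- counts$k
  if (eta == 0L) return(c(D_star = NA_real_, F_star = NA_real_))
  a <- .a1(n); b <- .a2(n)
  an1 <- a + 1 / n                         # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - a * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vF
  Fstar <- (k - ((n - 1) / n) * eta_s) / sqrt(uF * eta + vF * eta^2)
  c(D_star = Dstar, F_star = Fstar)
}

#' Haplotype table
#'
#' Collapses sequences to haplotypes compared on the retained
#' (complete-deletion) columns and tabulates their frequencies.
#'
#' @param alignment a [LocusAlignment-class].
#' @return named integer vector of haplotype counts, names are the retained
#'   haplotype strings, in decreasing count then lexicographic order.
#' @export
haplotypeTable <- function(alignment) {
  m <- .retainedMatrix(alignment)
  if (nrow(m) == 0L) return(setNames(integer(), character()))
  hap <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) hap <- rep("", nrow(m))
  tab <- table(hap)
  tab <- tab[order(-tab, names(tab))]
  setNames(as.integer(tab), names(tab))
}

#' Subsampling precision of nucleotide diversity
#'
#' Repeatedly draws `perPopulationN` individuals from every population of a
#' cohort, recomputes the cohort's pi at one marker from the drawn
#' individuals' haplotypes, and reports the relative standard deviation
#' (SD/mean) of pi across replicates -- the quantity used to judge whether a
#' per-population sample size is adequate.
#'
#' @param alignment the marker's [LocusAlignment-class].
#' @param samples sample metadata data.frame.
#' @param cohort `"wild"` or `"domestic"`.
#' @param perPopulationN individuals drawn per population.
#' @param nReps replicate draws.
#' @param seed integer seed.
#' @return list with `relativeSD`, `mean`, `sd`, and `flagged` (TRUE when any
#'   population was smaller than `perPopulationN`, forcing sampling with
#'   replacement, or when `nReps < 2`).
#' @export
subsamplePrecision <- function(alignment, samples, cohort, perPopulationN,
                               nReps = 200L, seed = 1L) {
  cohort <- match.arg(cohort, COHORT_LEVELS)
  stopifnot(perPopulationN >= 1L)
  m <- marker(alignment)
  smp <- samples[samples$cohort == cohort, , drop = FALSE]
  pops <- split(seq_len(nrow(smp)), smp$population)
  flagged <- any(lengths(pops) < perPopulationN) || nReps < 2L
  seqs <- sequences(alignment)
  set.seed(seed)
  pis <- vapply(seq_len(nReps), function(r) {
    rows <- unlist(lapply(pops, function(ix)
      if (length(ix) >= perPopulationN) sample(ix, perPopulationN)
      else sample(ix, perPopulationN, replace = TRUE)))
    ids <- unlist(lapply(smp[[m]][rows], .parseHapIds), use.names = FALSE)
    sub <- seqs[match(ids, names(seqs))]
    names(sub) <- make.unique(names(sub))  # replacement draws repeat ids
    nucleotideDiversity(methods::new("LocusAlignment", marker = m, seqs = sub))
  }, numeric(1))
  mu <- mean(pis); s <- if (nReps >= 2L) sd(pis) else 0
  list(relativeSD = if (mu > 0) s / mu else 0, mean = mu, sd = s,
       flagged = flagged)
}

#' Per-marker, per-cohort diversity summary table
#'
#' Computes, for every marker and cohort, the row of the standard multi-locus
#' summary: N, S, pi, Watterson's theta with its site-bootstrap interval,
#' Tajima's D, Fu and Li's D* and F*, and the haplotype count.  Values are on
#' their natural per-site scale; display scaling (x 10^3) is left to the
#' reporting layer.
#'
#' @param dataset a [MultiLocusDataset-class].
#' @param nBoot bootstrap resamples for the theta interval.
#' @param seed integer seed.
#' @return data.frame with one row per marker x cohort.
#' @export
diversitySummary <- function(dataset, nBoot = 1000L, seed = 1L) {
  rows <- list()
  for (m in names(alignments(dataset))) {
    for (ch in COHORT_LEVELS) {
      aln <- cohortSlice(alignments(dataset)[[m]], samples(dataset), ch)
      if (nSequences(aln) < 2L) next
      cnt <- siteCounts(aln)
      th <- wattersonTheta(aln, nBoot = nBoot, seed = seed)
      fl <- if (cnt$n >= 3L) fuLiStars(cnt) else c(D_star = NA_real_, F_star = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, cohort = ch, N = cnt$n, S = cnt$S,
        pi = if (cnt$L_effective) nucleotideDiversity(cnt) else NA_real_,
        theta_w = th$theta, theta_low = th$ci[1L], theta_high = th$ci[2L],
        D = tajimasD(cnt), D_star = unname(fl["D_star"]),
        F_star = unname(fl["F_star"]),
        n_haplotypes = length(haplotypeTable(aln)),
        L_effective = cnt$L_effective)
    }
  }
  do.call(rbind, rows)
}
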