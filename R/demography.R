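# Effective-migrant arithmetic and rejection-ABC inference of sex-biased
# wild-to-domestic gene flow.

#' Effective migrants per generation
#'
#' `M_N = M * theta`: the mutation-scaled migration rate `M = m/mu`
#' multiplied by the scaled diversity `theta` (`4*Ne*mu` for autosomes,
#' `2*Nf*mu` for mtDNA) of the receiving population.  Because both factors
#' are scaled by the same mutation rate, `mu` cancels and `M_N` counts
#' migrants (`4*Ne*m` or `2*Nf*m`) directly.
#'
#' @param M scaled migration rate (`m/mu`), nonnegative.
#' @param theta scaled diversity of the receiving population, nonnegative.
#' @return `M * theta`.
#' @export
effectiveMigrants <- function(M, theta) {
  if (any(M < 0) || any(theta < 0))
    stop("domain error: M and theta must be nonnegative")
  M * theta
}

# Fast per-locus summaries straight from the simulator's 0/1 matrix.
# Returns c(pi_wild, pi_dom, S_dom, D_dom, fst); NA-free (undefined -> 0),
# per-site pi.
.rawLocusSummaries <- function(G, deme, locusLen) {
  iW <- deme == "wild"; iD <- deme == "domestic"
  nW <- sum(iW); nD <- sum(iD)
  piOf <- function(idx, n) {
    if (n < 2L || ncol(G) == 0L) return(0)
    c1 <- colSums(G[idx, , drop = FALSE])
    sum(c1 * (n - c1)) / choose(n, 2) / locusLen
  }
  piW <- piOf(iW, nW); piD <- piOf(iD, nD)
  SD <- if (nD > 0L && ncol(G))
    sum(colSums(G[iD, , drop = FALSE]) %% nD != 0L) else 0L
  D <- 0
  if (nD >= 4L && SD > 0L) {
    cD <- colSums(G[iD, , drop = FALSE])
    seg <- cD %% nD != 0L
    k <- sum(cD[seg] * (nD - cD[seg])) / choose(nD, 2)
    cc <- .tajimaConstants(nD)
    D <- (k - SD / cc$a1) / sqrt(cc$e1 * SD + cc$e2 * SD * (SD - 1))
  }
  fst <- 0
  if (nW >= 2L && nD >= 2L && ncol(G)) {
    cW <- colSums(G[iW, , drop = FALSE]); cD <- colSums(G[iD, , drop = FALSE])
    hw <- (sum(cW * (nW - cW)) / choose(nW, 2) +
             sum(cD * (nD - cD)) / choose(nD, 2)) / 2
    pW <- cW / nW; pD <- cD / nD
    hb <- sum(pW * (1 - pD) + pD * (1 - pW))
    if (hb > 0) fst <- 1 - hw / hb
  }
  c(pi_wild = piW, pi_dom = piD, S_dom = as.numeric(SD), D_dom = D, fst = fst)
}

# Summary vector for one simulated dataset: per inheritance mode, the
# locus-averaged c(pi_wild, pi_dom, S_dom, D_dom, fst).
.simSummaries <- function(cfg, seed) {
  set.seed(seed)
  locusSeeds <- sample.int(.Machine$integer.max - 1L, nrow(cfg@loci))
  acc <- list(autosomal = NULL, mtDNA = NULL)
  for (i in seq_len(nrow(cfg@loci))) {
    mode <- cfg@loci$inheritance[i]
    ploidy <- if (mode == "mtDNA") 1L else 2L
    set.seed(locusSeeds[i])
    raw <- .simLocusRaw(cfg, cfg@loci$length[i], mode,
                        ploidy * cfg@samplesWild, ploidy * cfg@samplesDom)
    acc[[mode]] <- rbind(acc[[mode]],
                         .rawLocusSummaries(raw$G, raw$deme, cfg@loci$length[i]))
  }
  out <- c()
  for (mode in c("mtDNA", "autosomal")) {
    v <- if (is.null(acc[[mode]])) rep(0, 5) else colMeans(acc[[mode]])
    names(v) <- paste0(mode, "_", c("pi_wild", "pi_dom", "S_dom", "D_dom", "fst"))
    out <- c(out, v)
  }
  out
}

#' Observed summary statistics for ABC
#'
#' The fixed summary vector used by [abcSexBias()]: for each inheritance mode
#' (mtDNA, autosomal), the locus-averaged per-site pi of each cohort, the
#' domestic segregating-site count, the domestic Tajima's D and Hudson's
#' F_ST (undefined statistics enter as 0 so the vector has fixed length).
#'
#' @param dataset a [MultiLocusDataset-class].
#' @return named numeric vector of 10 summaries.
#' @export
abcSummaries <- function(dataset) {
  reg <- registryTable(registry(dataset))
  acc <- list(autosomal = NULL, mtDNA = NULL)
  for (m in names(alignments(dataset))) {
    aln <- alignments(dataset)[[m]]
    mode <- reg$inheritance[match(m, reg$name)]
    wild <- cohortSlice(aln, samples(dataset), "wild")
    dom <- cohortSlice(aln, samples(dataset), "domestic")
    cntW <- siteCounts(wild); cntD <- siteCounts(dom)
    piW <- if (cntW$L_effective) nucleotideDiversity(cntW) else 0
    piD <- if (cntD$L_effective) nucleotideDiversity(cntD) else 0
    D <- if (cntD$n >= 4L) tajimasD(cntD) else NA_real_
    if (is.na(D)) D <- 0
    pooled <- methods::new("LocusAlignment", marker = m,
                           seqs = c(sequences(wild), sequences(dom)))
    fst <- hudsonFst(pooled, c(rep("wild", nSequences(wild)),
                               rep("domestic", nSequences(dom))))
    if (is.na(fst)) fst <- 0
    acc[[mode]] <- rbind(acc[[mode]], c(piW, piD, cntD$S, D, fst))
  }
  out <- c()
  for (mode in c("mtDNA", "autosomal")) {
    v <- if (is.null(acc[[mode]])) rep(0, 5) else colMeans(acc[[mode]])
    names(v) <- paste0(mode, "_", c("pi_wild", "pi_dom", "S_dom", "D_dom", "fst"))
    out <- c(out, v)
  }
  out
}

#' Rejection-ABC inference of sex-biased migration
#'
#' Draws `(mF, mM, founderSize)` from their priors (uniform on log10 scale
#' for the migration rates, uniform for the founder size), simulates a
#' dataset-shaped summary vector under each draw with the structured
#' coalescent, standardizes every summary by its prior-predictive standard
#' deviation, and accepts the `acceptFraction` of draws closest to the
#' observed summaries in Euclidean distance.  The headline output is the
#' posterior probability that the male migration rate exceeds the female
#' one, `P(mM > mF | data)`.  Summaries with zero prior-predictive variance
#' are dropped with a warning.
#'
#' This is a desk-scale rejection sampler over the package's own simulator;
#' outputs are labelled as ABC estimates, not genealogy-MCMC estimates.
#'
#' @param observed summary vector from [abcSummaries()] (or a
#'   [MultiLocusDataset-class], which is summarized first).
#' @param baseConfig a [SimConfig-class] fixing all nuisance parameters and
#'   the locus/sample design used for the simulations.
#' @param priors list with `log10mF`, `log10mM` (ranges on log10 migration
#'   rates) and `founderSize` (range).
#' @param nSims number of prior draws.
#' @param acceptFraction fraction of draws accepted (e.g. 0.02).
#' @param seed integer seed.
#' @return an [AbcPosterior-class].
#' @export
abcSexBias <- function(observed, baseConfig,
                       priors = list(log10mF = c(-3.7, -2),
                                     log10mM = c(-3.7, -2),
                                     founderSize = c(150, 1500)),
                       nSims = 2000L, acceptFraction = 0.02, seed = 1L) {
  if (is(observed, "MultiLocusDataset")) observed <- abcSummaries(observed)
  stopifnot(acceptFraction > 0, acceptFraction <= 1)
  set.seed(seed)
  simSeeds <- sample.int(.Machine$integer.max - 1L, nSims)
  mF <- 10^runif(nSims, priors$log10mF[1L], priors$log10mF[2L])
  mM <- 10^runif(nSims, priors$log10mM[1L], priors$log10mM[2L])
  fs <- runif(nSims, priors$founderSize[1L], priors$founderSize[2L])
  sims <- matrix(NA_real_, nSims, length(observed),
                 dimnames = list(NULL, names(observed)))
  for (i in seq_len(nSims)) {
    cfg <- baseConfig
    cfg@mF <- mF[i]; cfg@mM <- mM[i]; cfg@founderSize <- round(fs[i])
    sims[i, ] <- .simSummaries(cfg, simSeeds[i])
  }
  sdv <- apply(sims, 2L, sd)
  dropped <- colnames(sims)[sdv == 0 | is.na(sdv)]
  if (length(dropped))
    warning("dropping zero-variance summaries: ",
            paste(dropped, collapse = ", "))
  keep <- sdv > 0 & !is.na(sdv)
  z <- sweep(sims[, keep, drop = FALSE], 2L, sdv[keep], "/")
  zObs <- observed[keep] / sdv[keep]
  dist <- sqrt(rowSums(sweep(z, 2L, zObs, "-")^2))
  nAccept <- max(1L, round(acceptFraction * nSims))
  sel <- order(dist)[seq_len(nAccept)]
  draws <- data.frame(mF = mF[sel], mM = mM[sel],
                      founderSize = round(fs[sel]), distance = dist[sel])
  methods::new("AbcPosterior", draws = draws,
               acceptFraction = acceptFraction, nSims = as.numeric(nSims),
               priors = priors, pMaleBiased = mean(draws$mM > draws$mF),
               dropped = dropped)
}

#' Base configuration of the packaged sex-bias recovery experiment
#'
#' The design used by the package's ABC validation: six intergenic autosomal
#' loci of 800 bp plus one 1,000-bp mtDNA locus, 15 wild and 20 domestic
#' individuals, a hard founder phase, and the backcross demography with the
#' true female rate placed mid-prior -- the regime in which the single
#' mitochondrial genealogy is most informative about the direction of sex
#' bias.
#'
#' @param seed integer seed stored in the config.
#' @return a [SimConfig-class].
#' @export
abcRecoveryConfig <- function(seed = 1L) {
  loci <- defaultLoci()[c(rep(11:14, length.out = 6L), 15L), ]
  loci$name <- c(sprintf("a%02d", 1:6), "mt1")
  loci$length <- c(rep(800L, 6L), 1000L)
  scenarioConfig("backcross", seed = seed, loci = loci, founderSize = 200,
                 samplesWild = 15, samplesDom = 20)
}
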