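# Structured-coalescent simulator for the domestication-bottleneck +
# sex-biased backcross demography.
#
# Backward in time there are two demes, wild and domestic.  Lineages sampled
# in the domestic deme migrate (trace their ancestry) into the wild deme at a
# per-generation rate set by the inheritance mode: the sex-averaged
# (mF + mM)/2 for autosomes, the female rate mF for mtDNA.  The domestic deme
# has diploid size nDom until the founding phase [tDom - tBottleneck, tDom],
# where it shrinks to founderSize, and merges into the wild deme at tDom.
# Coalescence within a deme of diploid size N runs at rate choose(k,2)/C with
# copy number C = 2N for autosomes and C = femaleFraction * N (the female
# count) for mtDNA, so that E[pi] = 4*N*mu and 2*N_f*mu respectively.
# Mutations are laid on the realized genealogy as a Poisson process of rate
# mu * length per generation per lineage, at infinite-sites positions drawn
# without replacement along the locus.

#' Build a simulation configuration
#'
#' @param preset one of `"backcross"` (domestication bottleneck plus strongly
#'   male-biased wild-to-domestic introgression -- the demography that yields
#'   depressed mtDNA but undiminished nuclear diversity in the domestic
#'   cohort), `"bottleneck_only"` (a mild founder event, no migration) or
#'   `"panmictic"` (a single wild population; the neutral-calibration
#'   control).
#' @param ... any [SimConfig-class] slot to override, e.g. `seed`, `loci`,
#'   `samplesWild`.
#' @return a validated [SimConfig-class].
#' @examples
#' scenarioConfig("backcross", seed = 7)
#' @export
scenarioConfig <- function(preset = c("backcross", "bottleneck_only", "panmictic"),
                           ...) {
  preset <- match.arg(preset)
  defaults <- list(
    nWild = 20000, nDom = 20000, founderSize = 300, tDom = 1000,
    tBottleneck = 500, mF = 5e-4, mM = 8e-3, muNuclear = 6.25e-8,
    muMt = 1.3e-6, femaleFraction = 0.5, loci = defaultLoci(),
    samplesWild = 30, samplesDom = 50, seed = 1)
  if (preset == "bottleneck_only") {
    defaults$founderSize <- 5000
    defaults$mF <- 0; defaults$mM <- 0
  }
  if (preset == "panmictic") {
    defaults$mF <- 0; defaults$mM <- 0
    defaults$tDom <- 0; defaults$tBottleneck <- 0
    defaults$samplesDom <- 0
  }
  args <- list(...)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("config error: unknown SimConfig field(s): ",
         paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  cfg <- do.call(methods::new, c(list("SimConfig"), defaults))
  methods::validObject(cfg)
  cfg
}

#' Default locus panel emulating a multi-marker survey
#'
#' Fourteen unlinked autosomal markers of 350--2000 bp (eight functional
#' genes, two pseudogenes, four intergenic regions) plus one mtDNA
#' control-region locus -- the shape of the study design this package
#' emulates.
#'
#' @return data.frame with columns `name`, `length`, `inheritance`,
#'   `functional_class`.
#' @export
defaultLoci <- function() {
  data.frame(
    name = c(sprintf("nuc%02d", 1:14), "mt1"),
    length = c(1971, 645, 583, 759, 568, 650, 578, 784, 669, 635,
               350, 641, 506, 520, 1200),
    inheritance = c(rep("autosomal", 14), "mtDNA"),
    functional_class = c(rep("functional_gene", 8), rep("pseudogene", 2),
                         rep("intergenic", 4), "control_region"))
}

# mode-specific copy number of a deme of diploid size N
.copyNumber <- function(N, mode, femaleFraction) {
  if (mode == "mtDNA") femaleFraction * N else 2 * N
}

# Core genealogy + infinite-sites engine for one locus.  Returns the 0/1
# derived-allele matrix (haplotypes x segregating sites), the deme of each
# sampled haplotype, and genealogy summaries.  RNG state is taken as-is.
.simLocusRaw <- function(cfg, locusLen, mode, nWildHap, nDomHap) {
  mu <- if (mode == "mtDNA") cfg@muMt else cfg@muNuclear
  mig <- if (mode == "mtDNA") cfg@mF else (cfg@mF + cfg@mM) / 2
  cWild <- .copyNumber(cfg@nWild, mode, cfg@femaleFraction)
  cDom <- .copyNumber(cfg@nDom, mode, cfg@femaleFraction)
  cFounder <- .copyNumber(cfg@founderSize, mode, cfg@femaleFraction)
  nTot <- nWildHap + nDomHap
  if (nTot == 0L)
    return(list(G = matrix(0L, 0L, 0L), deme = character(),
                tmrca = NA_real_, totalBranch = 0, nMigrations = 0L))
  deme <- c(rep(1L, nWildHap), rep(2L, nDomHap))   # 1 wild, 2 domestic
  if (cfg@tDom <= 0) deme[] <- 1L   # no domestic deme exists at sampling time
  desc <- as.list(seq_len(nTot))
  birth <- numeric(nTot)
  alive <- rep(TRUE, nTot)
  edgeDesc <- vector("list", 2L * nTot)
  edgeLen <- numeric(2L * nTot)
  nEdge <- 0L
  t <- 0
  b1 <- cfg@tDom - cfg@tBottleneck
  b2 <- cfg@tDom
  nMig <- 0L
  while (sum(alive) > 1L) {
    ia <- which(alive)
    kW <- sum(deme[ia] == 1L); kD <- sum(deme[ia] == 2L)
    domSize <- if (t >= b1 && t < b2) cFounder else cDom
    rateCW <- choose(kW, 2) / cWild
    rateCD <- if (t < b2) choose(kD, 2) / domSize else 0
    rateM <- if (t < b2) kD * mig else 0
    total <- rateCW + rateCD + rateM
    if (total == 0) {
      # all lineages stranded in the domestic deme with no events possible
      # before the merge; jump to the merge time
      t <- b2
      deme[ia] <- 1L
      next
    }
    dt <- rexp(1L, total)
    boundary <- if (t < b1) b1 else if (t < b2) b2 else Inf
    if (t + dt > boundary) {
      t <- boundary
      if (boundary == b2) deme[ia] <- 1L   # domestic deme merges into wild
      next
    }
    t <- t + dt
    u <- runif(1L) * total
    if (u < rateCW + rateCD) {             # coalescence
      d <- if (u < rateCW) 1L else 2L
      cand <- ia[deme[ia] == d]
      pair <- cand[sample.int(length(cand), 2L)]
      for (x in pair) {
        nEdge <- nEdge + 1L
        edgeDesc[[nEdge]] <- desc[[x]]
        edgeLen[nEdge] <- t - birth[x]
        alive[x] <- FALSE
      }
      desc[[pair[1L]]] <- c(desc[[pair[1L]]], desc[[pair[2L]]])
      alive[pair[1L]] <- TRUE
      birth[pair[1L]] <- t
    } else {                               # domestic -> wild lineage migration
      cand <- ia[deme[ia] == 2L]
      x <- cand[sample.int(length(cand), 1L)]
      deme[x] <- 1L
      nMig <- nMig + 1L
    }
  }
  tmrca <- t
  lens <- edgeLen[seq_len(nEdge)]
  descs <- edgeDesc[seq_len(nEdge)]
  totalBranch <- sum(lens)
  nMut <- rpois(nEdge, mu * locusLen * lens)
  tot <- sum(nMut)
  if (tot > locusLen) {                       # infinite-sites saturation guard
    keep <- sort(sample.int(tot, locusLen))
    edgeOf <- rep(seq_len(nEdge), nMut)[keep]
  } else {
    edgeOf <- rep(seq_len(nEdge), nMut)
  }
  S <- length(edgeOf)
  G <- matrix(0L, nTot, S)
  if (S > 0L) {
    pos <- sort(sample.int(locusLen, S))
    for (s in seq_len(S)) G[descs[[edgeOf[s]]], s] <- 1L
    attr(G, "positions") <- pos
  } else attr(G, "positions") <- integer()
  list(G = G, deme = c("wild", "domestic")[c(rep(1L, nWildHap), rep(2L, nDomHap))],
       tmrca = tmrca, totalBranch = totalBranch, nMigrations = nMig)
}

# Turn a 0/1 derived-allele matrix into concrete sequences on a random
# monomorphic reference.  RNG state is taken as-is.
.emitSequences <- function(G, locusLen, ids) {
  ref <- sample(BASES, locusLen, replace = TRUE)
  pos <- attr(G, "positions")
  alt <- vapply(pos, function(p) sample(setdiff(BASES, ref[p]), 1L), "")
  out <- vapply(seq_len(nrow(G)), function(i) {
    s <- ref
    hit <- pos[G[i, ] == 1L]
    if (length(hit)) s[hit] <- alt[G[i, ] == 1L]
    paste(s, collapse = "")
  }, "")
  setNames(out, ids)
}

#' Simulate one locus under the configured demography
#'
#' Runs the two-deme structured coalescent for a single locus and writes the
#' resulting infinite-sites haplotypes on a random monomorphic reference.
#'
#' @param config a [SimConfig-class].
#' @param locus locus name (a row of `config@loci`) or a one-row data.frame
#'   with `name`, `length`, `inheritance`.
#' @param nWildHap,nDomHap numbers of haplotypes to sample per deme; defaults
#'   follow the config's individual counts and the locus ploidy.
#' @param seed integer seed (default: the config seed).
#' @return list with `wild` and `domestic` [LocusAlignment-class] objects and
#'   `truth` (list: `tmrca`, `totalBranch`, `nMigrations`, `deme`,
#'   `positions`, `S`).
#' @export
simulateLocus <- function(config, locus, nWildHap = NULL, nDomHap = NULL,
                          seed = config@seed) {
  if (is.character(locus)) {
    hit <- match(locus, config@loci$name)
    if (is.na(hit)) stop("config error: unknown locus: ", locus)
    locus <- config@loci[hit, , drop = FALSE]
  }
  mode <- locus$inheritance
  ploidy <- if (mode == "mtDNA") 1L else 2L
  if (is.null(nWildHap)) nWildHap <- ploidy * config@samplesWild
  if (is.null(nDomHap)) nDomHap <- ploidy * config@samplesDom
  set.seed(seed)
  raw <- .simLocusRaw(config, locus$length, mode, nWildHap, nDomHap)
  ids <- c(if (nWildHap) paste0("w", seq_len(nWildHap)),
           if (nDomHap) paste0("d", seq_len(nDomHap)))
  seqs <- .emitSequences(raw$G, locus$length, ids)
  mk <- function(which) {
    keep <- raw$deme == which
    LocusAlignment(locus$name, seqs[keep])
  }
  list(wild = mk("wild"), domestic = mk("domestic"),
       truth = list(tmrca = raw$tmrca, totalBranch = raw$totalBranch,
                    nMigrations = raw$nMigrations, deme = raw$deme,
                    positions = attr(raw$G, "positions"),
                    S = ncol(raw$G)))
}

#' Simulate a complete multi-locus dataset
#'
#' Simulates every locus of the configuration independently (per-locus seeds
#' are derived deterministically from the config seed), assembles diploid
#' individuals by pairing autosomal haplotypes (`<ind>_a`/`<ind>_b`) and
#' attaching one mtDNA haplotype (`<ind>_mt`), and assigns region and
#' population labels uniformly at random among the seven region codes (no
#' spatial structure -- the regime where a clustering analysis finds K = 1).
#'
#' @param config a [SimConfig-class].
#' @return list with `dataset` (a validated [MultiLocusDataset-class]) and
#'   `truth` (per-locus genealogy summaries).
#' @export
simulateDataset <- function(config) {
  set.seed(config@seed)
  loci <- config@loci
  locusSeeds <- sample.int(.Machine$integer.max - 1L, nrow(loci) + 1L)
  nW <- config@samplesWild; nD <- config@samplesDom
  indIds <- c(if (nW) sprintf("W%03d", seq_len(nW)),
              if (nD) sprintf("D%03d", seq_len(nD)))
  cohort <- c(rep("wild", nW), rep("domestic", nD))
  set.seed(locusSeeds[nrow(loci) + 1L])
  group <- sample(REGION_CODES, nW + nD, replace = TRUE)
  site <- sample(1:2, nW + nD, replace = TRUE)
  population <- ifelse(cohort == "wild", paste0(group, "_site", site),
                       paste0(group, "_breed", site))
  smp <- data.frame(individual_id = indIds, cohort = cohort, group = group,
                    population = population, stringsAsFactors = FALSE)
  alns <- list(); truth <- list()
  for (i in seq_len(nrow(loci))) {
    mode <- loci$inheritance[i]
    ploidy <- if (mode == "mtDNA") 1L else 2L
    nWH <- ploidy * nW; nDH <- ploidy * nD
    set.seed(locusSeeds[i])
    raw <- .simLocusRaw(config, loci$length[i], mode, nWH, nDH)
    inds <- c(rep(indIds[seq_len(nW)], each = ploidy),
              rep(indIds[nW + seq_len(nD)], each = ploidy))
    suffix <- if (ploidy == 2L) rep(c("_a", "_b"), nW + nD) else "_mt"
    ids <- paste0(inds, suffix)
    seqs <- .emitSequences(raw$G, loci$length[i], ids)
    alns[[loci$name[i]]] <- LocusAlignment(loci$name[i], seqs)
    smp[[loci$name[i]]] <- vapply(indIds, function(ind)
      paste(ids[inds == ind], collapse = ","), "")
    truth[[loci$name[i]]] <- list(tmrca = raw$tmrca,
                                  totalBranch = raw$totalBranch,
                                  nMigrations = raw$nMigrations,
                                  S = ncol(raw$G), deme = raw$deme)
  }
  reg <- MarkerRegistry(data.frame(
    name = loci$name, chromosome = as.character(seq_len(nrow(loci))),
    inheritance = loci$inheritance, length = loci$length,
    functional_class = loci$functional_class))
  ds <- MultiLocusDataset(alns, smp, reg, check = TRUE)
  list(dataset = ds, truth = truth)
}
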