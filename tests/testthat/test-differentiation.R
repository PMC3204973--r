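# Hudson's F_ST and hierarchical AMOVA.

test_that("hudsonFst hits the boundary cases exactly", {
  # literally duplicated allele sets: the sample estimator's exact value is
  # -1/(n-1) per cohort size n (its small-sample bias), approaching 0 as n
  # grows
  for (k in c(1L, 2L, 20L)) {
    n <- 2L * k   # per-cohort size; each cohort holds k of each allele
    cohortSet <- c(rep("AAAA", k), rep("AAAT", k))
    seqs <- setNames(c(cohortSet, cohortSet), paste0("s", seq_len(2 * n)))
    lab <- rep(c("w", "d"), each = n)
    expect_equal(hudsonFst(LocusAlignment("m", seqs), lab), -1 / (n - 1),
                 tolerance = 1e-12)
  }
  # fixed difference with no within-cohort variation -> 1
  seqs <- c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAT", b2 = "AAAT")
  expect_equal(hudsonFst(LocusAlignment("m", seqs),
                         c("w", "w", "d", "d")), 1)
  # monomorphic between -> NA
  seqs <- c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA", b2 = "AAAA")
  expect_true(is.na(hudsonFst(LocusAlignment("m", seqs),
                              c("w", "w", "d", "d"))))
})

test_that("hudsonFst equals the brute-force pairwise enumeration", {
  set.seed(8)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 8 * 30, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1)), nrow = 8)
    strs <- apply(mat, 1, paste, collapse = "")
    names(strs) <- paste0("s", 1:8)
    lab <- rep(c("w", "d"), each = 4)
    hw <- (oracleMeanPairwise(strs[1:4]) + oracleMeanPairwise(strs[5:8])) / 2
    hb <- oracleMeanPairwise(strs[1:4], strs[5:8])
    expect_equal(hudsonFst(LocusAlignment("m", strs), lab), 1 - hw / hb,
                 tolerance = 1e-12)
  }
  # symmetry under cohort relabeling
  strs <- setNames(c("AAAA", "AATA", "TAAA", "TATA", "AAAT", "AATT"),
                   paste0("s", 1:6))
  lab <- c("w", "w", "w", "d", "d", "d")
  expect_equal(hudsonFst(LocusAlignment("m", strs), lab),
               hudsonFst(LocusAlignment("m", strs),
                         ifelse(lab == "w", "d", "w")))
})

test_that("AMOVA components match the hand-solved balanced system", {
  # 2 groups x 2 pops x 3 sequences with deterministic structured sequences
  set.seed(3)
  base <- c("AAAAAAAAAAAA", "CCCCAAAAAAAA", "CCCCGGGGAAAA", "CCCCGGGGTTTT")
  seqs <- character(); grp <- character(); pop <- character()
  for (g in 1:2) for (p in 1:2) for (i in 1:3) {
    s <- strsplit(base[(g - 1) * 2 + p], "")[[1]]
    flip <- sample(12, 1)  # one private mutation per sequence
    s[flip] <- setdiff(c("A", "C", "G", "T"), s[flip])[i %% 3 + 1]
    seqs <- c(seqs, paste(s, collapse = ""))
    grp <- c(grp, paste0("g", g)); pop <- c(pop, paste0("p", g, p))
  }
  names(seqs) <- paste0("s", seq_along(seqs))
  aln <- LocusAlignment("m", seqs)
  part <- data.frame(group = grp, population = pop)
  res <- amova(aln, part, nPerm = 0)
  m <- do.call(rbind, strsplit(seqs, ""))
  d2 <- matrix(0, 12, 12)
  for (i in 1:11) for (j in (i + 1):12)
    d2[i, j] <- d2[j, i] <- sum(m[i, ] != m[j, ])
  want <- oracleAmovaBalanced(d2, grp, pop)
  expect_equal(unname(res@components), unname(want), tolerance = 1e-9)
  # method-of-moments identity: SSD total = sum of stratum SSDs
  ssdT <- sum(d2) / (2 * 12)
  expect_equal(sum(res@ssd), ssdT, tolerance = 1e-9)
  # Phi definitions from the components
  tot <- sum(want)
  expect_equal(unname(res@phi["phi_CT"]), unname(want["sigA"] / tot),
               tolerance = 1e-9)
  expect_equal(unname(res@phi["phi_ST"]),
               unname((want["sigA"] + want["sigB"]) / tot), tolerance = 1e-9)
})

test_that("AMOVA handles degenerate inputs as specified", {
  seqs <- setNames(rep("ACGT", 8), paste0("s", 1:8))
  part <- data.frame(group = rep(c("g1", "g2"), each = 4),
                     population = rep(c("p1", "p2", "p3", "p4"), each = 2))
  res <- amova(LocusAlignment("m", seqs), part, nPerm = 10)
  expect_true(all(is.na(res@phi)))       # no molecular variation
  expect_equal(sum(res@ssd), 0)
  # one population per group -> Phi_SC undefined
  seqs2 <- setNames(c("AAAA", "AATA", "TAAA", "TTTA", "TTAA", "TTTT"),
                    paste0("s", 1:6))
  part2 <- data.frame(group = rep(c("g1", "g2"), each = 3),
                      population = rep(c("p1", "p2"), each = 3))
  res2 <- amova(LocusAlignment("m", seqs2), part2, nPerm = 20, seed = 4)
  expect_true(is.na(res2@phi["phi_SC"]))
  expect_false(is.na(res2@phi["phi_CT"]))
  expect_error(amova(LocusAlignment("m", seqs),
                     data.frame(group = "g", population = "p")[rep(1, 8), ]),
               "at least 2 populations")
})

test_that("AMOVA permutation p-values are valid and deterministic", {
  sim <- simulateLocus(testConfig(seed = 2), "mt1", seed = 31)
  seqs <- c(as.character(sequences(sim$wild)), as.character(sequences(sim$domestic)))
  names(seqs) <- paste0("s", seq_along(seqs))
  n <- length(seqs)
  set.seed(5)
  part <- data.frame(group = sample(rep(c("g1", "g2"), length.out = n)),
                     population = sample(rep(paste0("p", 1:4), length.out = n)))
  part$population <- paste(part$group, part$population)  # nest pops in groups
  r1 <- amova(LocusAlignment("m", seqs), part, nPerm = 99, seed = 7)
  r2 <- amova(LocusAlignment("m", seqs), part, nPerm = 99, seed = 7)
  expect_identical(r1@pValues, r2@pValues)
  p <- r1@pValues[!is.na(r1@pValues)]
  expect_true(all(p >= 1 / 100 & p <= 1))
})

test_that("two-deme F_ST responds to migration as the coalescent predicts", {
  # deep split, no migration -> strongly positive; panmixia -> near zero
  cfgSplit <- scenarioConfig("backcross", seed = 1, mF = 0, mM = 0,
                             tDom = 200000, tBottleneck = 0, founderSize = 20000,
                             loci = data.frame(name = "L", length = 800,
                                               inheritance = "autosomal",
                                               functional_class = "intergenic"),
                             samplesWild = 8, samplesDom = 8)
  pooledFst <- function(sl) {
    w <- as.character(sequences(sl$wild)); d <- as.character(sequences(sl$domestic))
    pooled <- LocusAlignment("L", c(w, d))
    f <- hudsonFst(pooled, rep(c("w", "d"), c(length(w), length(d))))
    if (is.na(f)) 0 else f
  }
  fsts <- vapply(1:40, function(s)
    pooledFst(simulateLocus(cfgSplit, "L", seed = 1000 + s)), numeric(1))
  expect_gt(median(fsts), 0.5)
  cfgPan <- scenarioConfig("backcross", seed = 1, mF = 0.5, mM = 0.5,
                           tDom = 200000, tBottleneck = 0, founderSize = 20000,
                           loci = data.frame(name = "L", length = 800,
                                             inheritance = "autosomal",
                                             functional_class = "intergenic"),
                           samplesWild = 8, samplesDom = 8)
  fsts <- vapply(1:40, function(s)
    pooledFst(simulateLocus(cfgPan, "L", seed = 2000 + s)), numeric(1))
  expect_lt(abs(median(fsts)), 0.1)
})
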