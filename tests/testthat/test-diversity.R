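# Diversity and neutrality statistics.

test_that("siteCounts handles identity, derived and multi-allelic cases", {
  # 5 identical sequences
  a <- mkAln("ACGT", "ACGT", "ACGT", "ACGT", "ACGT")
  cnt <- siteCounts(a)
  expect_equal(cnt$S, 0L); expect_equal(cnt$eta, 0L); expect_equal(cnt$k, 0)
  # hand-enumerated case: 4 sequences, length 10, two polymorphic columns
  # pairwise diffs: h2 vs others at col 4, h3 vs others at col 2
  a <- mkAln("AAAAAAAAAA", "AAATAAAAAA", "ACAAAAAAAA", "AAAAAAAAAA")
  cnt <- siteCounts(a)
  expect_equal(cnt$S, 2L)
  expect_equal(cnt$eta, 2L)
  expect_equal(cnt$eta_s, 2L)
  expect_equal(cnt$k, 1.0)  # 6 pairs, diffs 1,1,0,2,1,1 -> 6/6
  expect_equal(cnt$k, oracleMeanPairwise(c("AAAAAAAAAA", "AAATAAAAAA",
                                           "ACAAAAAAAA", "AAAAAAAAAA")))
  # triallelic column contributes 1 to S and 2 to eta
  a <- mkAln("A", "C", "G", "A", "A", "A")
  cnt <- siteCounts(a)
  expect_equal(cnt$S, 1L); expect_equal(cnt$eta, 2L); expect_equal(cnt$eta_s, 2L)
  # columns with gaps or N are completely deleted
  a <- mkAln("ACGT", "A-GT", "ACNT", "ACGA")
  expect_equal(siteCounts(a)$L_effective, 2L)
  expect_error(siteCounts(mkAln("ACGT")), "insufficient-data")
})

test_that("nucleotide diversity is k over effective length", {
  a <- mkAln(strrep("A", 100), paste0(strrep("A", 99), "T"))
  expect_equal(nucleotideDiversity(a), 0.01)
  expect_equal(nucleotideDiversity(mkAln("ACGT", "ACGT")), 0)
  allMissing <- mkAln("NN", "NN")
  expect_error(nucleotideDiversity(allMissing), "undefined-statistic")
})

test_that("Watterson's theta matches hand-computed values and pi at n=2", {
  # n=2 -> a1=1
  a2 <- mkAln(paste0(strrep("A", 97), "TTT"), strrep("A", 100))
  expect_equal(wattersonTheta(a2)$theta, 0.03)
  expect_equal(wattersonTheta(a2)$theta, nucleotideDiversity(a2))
  # n=4, S=3, L=100 -> 3 / (11/6 * 100)
  seqs <- c(strrep("A", 100),
            paste0("T", strrep("A", 99)),
            paste0("AT", strrep("A", 98)),
            paste0("AAT", strrep("A", 97)))
  th <- wattersonTheta(mkAln(seqs[1], seqs[2], seqs[3], seqs[4]))
  expect_equal(th$theta, 3 / ((1 + 1/2 + 1/3) * 100), tolerance = 1e-12)
  # bootstrap interval brackets the point estimate and is deterministic
  aln <- mkAln(seqs[1], seqs[2], seqs[3], seqs[4])
  b1 <- wattersonTheta(aln, nBoot = 200, seed = 5)
  b2 <- wattersonTheta(aln, nBoot = 200, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= b1$theta && b1$theta <= b1$ci[2])
})

test_that("Tajima's D agrees with an independent transcription of the constants", {
  # numerator vanishing forces D = 0: k = S/a1
  n <- 4; S <- 3; a1 <- 1 + 1/2 + 1/3
  cnt <- list(n = n, S = S, eta = S, eta_s = S, k = S / a1, L_effective = 100L)
  class(cnt) <- "SiteCounts"
  expect_equal(tajimasD(cnt), 0)
  # spec'd small case
  cnt$k <- 1.5
  expect_equal(tajimasD(cnt), oracleTajimasD(4, 3, 1.5), tolerance = 1e-9)
  expect_equal(tajimasD(cnt), -0.754, tolerance = 1e-3)
  # a grid of cases against the oracle
  for (n in c(4, 7, 12, 40)) for (S in c(1, 5, 20)) for (k in c(0.3, 2, 9)) {
    cnt <- list(n = n, S = S, eta = S, eta_s = 1L, k = k, L_effective = 500L)
    class(cnt) <- "SiteCounts"
    expect_equal(tajimasD(cnt), oracleTajimasD(n, S, k), tolerance = 1e-9)
  }
  # S = 0 is undefined, never 0
  mono <- siteCounts(mkAln("ACGT", "ACGT", "ACGT", "ACGT"))
  expect_true(is.na(tajimasD(mono)))
})

test_that("Fu & Li's D*/F* match the dual transcription and sign conventions", {
  mk <- function(n, eta, etaS, k) {
    cnt <- list(n = n, S = eta, eta = eta, eta_s = etaS, k = k,
                L_effective = 100L)
    class(cnt) <- "SiteCounts"
    cnt
  }
  # fixed small case from two independent transcriptions
  got <- fuLiStars(mk(6, 5, 2, 2.0))
  want <- oracleFuLi(6, 5, 2, 2.0)
  expect_equal(unname(got["D_star"]), unname(want["Dstar"]), tolerance = 1e-12)
  expect_equal(unname(got["F_star"]), unname(want["Fstar"]), tolerance = 1e-12)
  # broader grid
  for (n in c(5, 10, 25)) for (eta in c(2, 8, 30)) {
    etaS <- max(1, round(eta / 3))
    got <- fuLiStars(mk(n, eta, etaS, eta / 2))
    want <- oracleFuLi(n, eta, etaS, eta / 2)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
  # all mutations singletons -> D* < 0 for n > 3
  expect_lt(fuLiStars(mk(10, 10, 10, 1.8))["D_star"], 0)
  # eta = 0 -> not applicable
  expect_true(all(is.na(fuLiStars(siteCounts(mkAln("ACG", "ACG", "ACG"))))))
})

test_that("neutral coalescent data center D, D* and F* near zero", {
  cfg <- scenarioConfig("panmictic", seed = 42,
                        loci = data.frame(name = "L1", length = 1000,
                                          inheritance = "autosomal",
                                          functional_class = "intergenic"),
                        samplesWild = 15, samplesDom = 0)
  set.seed(42)
  seeds <- sample.int(1e8, 300)
  stats <- vapply(seeds, function(s) {
    sl <- simulateLocus(cfg, "L1", seed = s)
    cnt <- siteCounts(sl$wild)
    if (cnt$S == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(tajimasD(cnt), fuLiStars(cnt))
  }, numeric(3))
  expect_lt(abs(mean(stats[1, ], na.rm = TRUE)), 0.25)
  expect_lt(abs(mean(stats[2, ], na.rm = TRUE)), 0.25)
  expect_lt(abs(mean(stats[3, ], na.rm = TRUE)), 0.25)
})

test_that("haplotype tabulation collapses on retained columns", {
  expect_equal(unname(haplotypeTable(mkAln("ACGT", "ACGT", "ACGT"))), 3L)
  tab <- haplotypeTable(mkAln("ACGT", "ACGA", "ACGT"))
  expect_equal(unname(tab), c(2L, 1L))
  # gap column removed before collapsing: h2/h3 identical on retained columns
  tab <- haplotypeTable(mkAln("ACGT", "AC-T", "ACAT"))
  expect_equal(sum(tab), 3L)
  expect_equal(length(tab), 1L)
})

test_that("statistics are invariant to sequence order and site permutation", {
  sim <- simulateLocus(testConfig(seed = 9), "mt1", seed = 77)
  aln <- sim$wild
  m <- as.matrix(sequences(aln))
  set.seed(1)
  shuffledRows <- m[sample(nrow(m)), , drop = FALSE]
  shuffledCols <- m[, sample(ncol(m)), drop = FALSE]
  back <- function(mm) LocusAlignment("mt1", setNames(
    apply(mm, 1, paste, collapse = ""), paste0("s", seq_len(nrow(mm)))))
  c0 <- siteCounts(aln); c1 <- siteCounts(back(shuffledRows))
  c2 <- siteCounts(back(shuffledCols))
  for (f in c("S", "eta", "eta_s", "k", "L_effective")) {
    expect_equal(c1[[f]], c0[[f]])
    expect_equal(c2[[f]], c0[[f]])
  }
  expect_equal(tajimasD(c1), tajimasD(c0))
  expect_equal(fuLiStars(c2), fuLiStars(c0))
})

test_that("subsampling precision shrinks with per-population sample size", {
  cfg <- testConfig(seed = 21, nLoci = 1, wild = 24, dom = 4)
  sim <- simulateDataset(cfg)
  aln <- alignments(sim$dataset)[[1]]
  smp <- samples(sim$dataset)
  # full-sample draw is exact when every population is fully drawn
  r1 <- subsamplePrecision(aln, smp, "wild", perPopulationN = 1, nReps = 60,
                           seed = 3)
  r3 <- subsamplePrecision(aln, smp, "wild", perPopulationN = 3, nReps = 60,
                           seed = 3)
  expect_true(r3$flagged)  # some populations are smaller than 3
  expect_lte(r3$relativeSD, r1$relativeSD)
  r0 <- subsamplePrecision(aln, smp, "wild", perPopulationN = 1, nReps = 1,
                           seed = 3)
  expect_true(r0$flagged)
  expect_equal(r0$sd, 0)
})
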