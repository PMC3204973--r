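# Structured-coalescent simulator.

test_that("configs validate and presets differ as documented", {
  cfg <- scenarioConfig("backcross")
  expect_s4_class(cfg, "SimConfig")
  expect_gt(cfg@mM, cfg@mF)           # male-biased introgression
  b <- scenarioConfig("bottleneck_only")
  expect_equal(b@mF + b@mM, 0)
  p <- scenarioConfig("panmictic")
  expect_equal(p@samplesDom, 0)
  expect_error(scenarioConfig("backcross", founderSize = 0), "sizes")
  expect_error(scenarioConfig("backcross", tBottleneck = 2000, tDom = 1000),
               "tBottleneck")
  expect_error(scenarioConfig("backcross", bogus = 1), "unknown")
})

test_that("zero mutation rate gives identical haplotypes; seeds reproduce bytes", {
  cfg <- testConfig(seed = 3)
  cfg@muNuclear <- 0; cfg@muMt <- 0
  sl <- simulateLocus(cfg, "mt1")
  expect_equal(siteCounts(LocusAlignment("m", c(
    as.character(sequences(sl$wild)),
    setNames(as.character(sequences(sl$domestic)),
             paste0("d", seq_len(nSequences(sl$domestic)))))))$S, 0L)
  # determinism: same config and seed -> byte-identical datasets
  s1 <- simulateDataset(testConfig(seed = 12))
  s2 <- simulateDataset(testConfig(seed = 12))
  for (m in names(alignments(s1$dataset)))
    expect_identical(as.character(sequences(alignments(s1$dataset)[[m]])),
                     as.character(sequences(alignments(s2$dataset)[[m]])))
  expect_identical(samples(s1$dataset), samples(s2$dataset))
  # different seed -> different data
  s3 <- simulateDataset(testConfig(seed = 13))
  expect_false(identical(as.character(sequences(alignments(s1$dataset)[[1]])),
                         as.character(sequences(alignments(s3$dataset)[[1]]))))
})

test_that("panmictic mean S and pi match neutral expectations (small n)", {
  theta <- 0.005   # 4 N mu with the preset sizes
  L <- 500; n <- 10
  cfg <- scenarioConfig("panmictic", seed = 1,
                        loci = data.frame(name = "L", length = L,
                                          inheritance = "autosomal",
                                          functional_class = "intergenic"),
                        samplesWild = n / 2, samplesDom = 0)
  reps <- 300
  set.seed(7)
  seeds <- sample.int(1e8, reps)
  stats <- vapply(seeds, function(s) {
    sl <- simulateLocus(cfg, "L", seed = s)
    cnt <- siteCounts(sl$wild)
    c(cnt$S, cnt$k / L)
  }, numeric(2))
  a1 <- sum(1 / seq_len(n - 1))
  expS <- a1 * theta * L
  seS <- sd(stats[1, ]) / sqrt(reps)
  expect_lt(abs(mean(stats[1, ]) - expS), 3 * seS + 1e-9)
  sePi <- sd(stats[2, ]) / sqrt(reps)
  expect_lt(abs(mean(stats[2, ]) - theta), 3 * sePi + 1e-9)
})

test_that("mtDNA genealogies are shallower than autosomal at equal census size", {
  cfg <- scenarioConfig("panmictic", seed = 1,
                        loci = data.frame(name = c("A", "M"),
                                          length = c(500, 500),
                                          inheritance = c("autosomal", "mtDNA"),
                                          functional_class = "intergenic"),
                        samplesWild = 8, samplesDom = 0)
  set.seed(11)
  seeds <- sample.int(1e8, 120)
  tm <- vapply(seeds, function(s) {
    c(simulateLocus(cfg, "A", seed = s)$truth$tmrca,
      simulateLocus(cfg, "M", seed = s + 1)$truth$tmrca)
  }, numeric(2))
  # copy number N_f = N/2 versus 2N: a fourfold expected depth difference
  expect_lt(median(tm[2, ]), median(tm[1, ]) / 2)
})

test_that("simulated datasets carry the configured shape and truth labels", {
  cfg <- testConfig(seed = 8, nLoci = 2, wild = 5, dom = 7)
  sim <- simulateDataset(cfg)
  ds <- sim$dataset
  expect_equal(length(alignments(ds)), 3L)
  expect_silent(validateDataset(ds))
  # per-deme counts in truth match the metadata cohorts
  tr <- sim$truth$mt1
  expect_equal(sum(tr$deme == "wild"), 5L)
  expect_equal(sum(tr$deme == "domestic"), 7L)
  expect_equal(nSequences(cohortSlice(alignments(ds)$mt1, samples(ds), "wild")),
               5L)
  # autosomal: two haplotypes per individual, ids <ind>_a / <ind>_b
  ids <- names(sequences(alignments(ds)[[1]]))
  expect_true(all(grepl("_(a|b)$", ids)))
  expect_equal(sum(grepl("^W", ids)), 10L)
  # haplotype count equals the truth matrix's distinct row count
  aln <- alignments(ds)$mt1
  expect_equal(length(haplotypeTable(aln)),
               length(unique(as.character(sequences(aln)))))
  # migration counter: zero when migration is off
  cfg0 <- testConfig("bottleneck_only", seed = 4)
  expect_equal(simulateLocus(cfg0, "mt1")$truth$nMigrations, 0L)
})

test_that("the backcross preset depresses mtDNA but not autosomal diversity", {
  # scaled-down replicate check; the full 200-replicate contrast runs in the
  # acceptance suite
  ratios <- function(preset, n = 30) {
    loci <- defaultLoci()[c(11, 12, 15), ]
    vapply(seq_len(n), function(s) {
      cfg <- scenarioConfig(preset, seed = 5000 + s, loci = loci,
                            samplesWild = 10, samplesDom = 12)
      sim <- simulateDataset(cfg)
      div <- diversitySummary(sim$dataset, nBoot = 0)
      mt <- div$marker == "mt1"
      auto <- !mt
      pi <- function(sel, ch) mean(div$pi[sel & div$cohort == ch])
      c(pi("mt1" == div$marker, "domestic") / pi(mt, "wild"),
        pi(auto, "domestic") / pi(auto, "wild"))
    }, numeric(2))
  }
  bc <- ratios("backcross")
  expect_lt(median(bc[1, ], na.rm = TRUE), median(bc[2, ], na.rm = TRUE))
})
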