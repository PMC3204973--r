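# Alignment, metadata and registry I/O.

test_that("FASTA round-trip preserves sequences, ids and order", {
  a <- mkAln(s1 = "ACGTAC", s2 = "ACGTAA", s3 = "ANG-AA", marker = "m1")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLocusAlignment(a, f)
  b <- readLocusAlignment(f, "m1")
  expect_identical(as.character(sequences(b)), as.character(sequences(a)))
  expect_identical(names(sequences(b)), names(sequences(a)))
  expect_equal(alignmentLength(b), 6L)
})

test_that("alignment constructor enforces the invariants", {
  expect_s4_class(LocusAlignment("m", c(a = "ACGT", b = "ACGT")), "LocusAlignment")
  expect_error(LocusAlignment("m", c(a = "ACGT", b = "ACGTA", c = "ACGT")),
               "record 'b'")
  expect_error(LocusAlignment("m", c(a = "ACGT", a = "ACGT")), "duplicated")
  expect_error(LocusAlignment("m", c(a = "ACXT")), "outside")
  # lower case is normalized, not rejected
  expect_equal(as.character(sequences(LocusAlignment("m", c(a = "acgt")))[[1]]),
               "ACGT")
})

test_that("empty or missing FASTA files raise input errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_error(readLocusAlignment(f), "no records")
  expect_error(readLocusAlignment(file.path(tempdir(), "nope.fasta")),
               "no such file")
})

test_that("sample table validation catches bad cohorts, groups and id counts", {
  ds <- tinyDataset()
  smp <- samples(ds)
  expect_silent(validateSampleTable(smp, registry(ds)))
  bad <- smp; bad$group[1] <- "EUROPE"
  expect_error(validateSampleTable(bad), "unknown group code: EUROPE")
  bad <- smp; bad$cohort[1] <- "feral"
  expect_error(validateSampleTable(bad), "cohort")
  bad <- smp; bad$nucA[1] <- "W1_a"
  expect_error(validateSampleTable(bad, registry(ds)), "expected 2")
  bad <- smp; bad$mtA[1] <- "W1_mt,W1_mt2"
  expect_error(validateSampleTable(bad, registry(ds)), "expected 1")
})

test_that("packaged marker registry reproduces the published panel totals", {
  reg <- readMarkerRegistry(system.file("extdata",
    "nuclear_markers_registry.dcf", package = "mtnucdiv"))
  expect_equal(nrow(registryTable(reg)), 14L)
  tot <- registryTotals(reg)
  expect_equal(unname(tot["total_bp"]), 9859)
  expect_equal(unname(tot["coding_bp"]), 1872)
  expect_equal(unname(tot["noncoding_bp"]), 7987)
})

test_that("registry round-trips through its DCF format and rejects overlaps", {
  reg <- readMarkerRegistry(system.file("extdata",
    "nuclear_markers_registry.dcf", package = "mtnucdiv"))
  f <- withr::local_tempfile(fileext = ".dcf")
  writeMarkerRegistry(reg, f)
  reg2 <- readMarkerRegistry(f)
  expect_equal(registryTable(reg2), registryTable(reg))
  expect_equal(codingIntervals(reg2, "GH"), codingIntervals(reg, "GH"))
  # empty registry -> empty list, totals 0
  writeLines(character(), f)
  reg0 <- readMarkerRegistry(f)
  expect_equal(nrow(registryTable(reg0)), 0L)
  expect_equal(unname(registryTotals(reg0)), c(0, 0, 0))
  # overlapping intervals are a config error
  expect_error(MarkerRegistry(
    data.frame(name = "x", chromosome = "1", inheritance = "autosomal",
               length = 100L, functional_class = "functional_gene"),
    coding = list(x = data.frame(start = c(1L, 5L), end = c(10L, 20L),
                                 frame = 1L, strand = "+"))) |>
      methods::validObject(), "overlapping")
})

test_that("cohortSlice returns the cohort's haplotypes in alignment order", {
  ds <- tinyDataset()
  w <- cohortSlice(alignments(ds)$mtA, samples(ds), "wild")
  expect_equal(nSequences(w), 3L)
  expect_equal(names(sequences(w)), c("W1_mt", "W2_mt", "W3_mt"))
  d <- cohortSlice(alignments(ds)$nucA, samples(ds), "domestic")
  expect_equal(nSequences(d), 4L)  # 2 individuals x 2 haplotypes
  # cohort with no samples -> empty alignment
  smp0 <- samples(ds)[samples(ds)$cohort == "wild", ]
  expect_equal(nSequences(cohortSlice(alignments(ds)$mtA, smp0, "domestic")), 0L)
  # orphan reference -> validation error
  smpBad <- samples(ds); smpBad$mtA[1] <- "missing_id"
  expect_error(cohortSlice(alignments(ds)$mtA, smpBad, "wild"), "absent")
})

test_that("simulated datasets survive a write/read round-trip and validate", {
  sim <- simulateDataset(testConfig(seed = 11, wild = 4, dom = 5))
  dir <- withr::local_tempdir()
  writeDataset(sim$dataset, dir)
  back <- readDataset(dir)
  expect_silent(validateDataset(back))
  expect_equal(samples(back), samples(sim$dataset))
  for (m in names(alignments(back)))
    expect_identical(as.character(sequences(alignments(back)[[m]])),
                     as.character(sequences(alignments(sim$dataset)[[m]])))
  # slicing by cohort matches the simulator's per-deme sample sizes
  w <- cohortSlice(alignments(back)$mt1, samples(back), "wild")
  expect_equal(nSequences(w), 4L)
  a <- cohortSlice(alignments(back)[[1]], samples(back), "domestic")
  expect_equal(nSequences(a), 10L)
})

test_that("validateDataset cross-checks metadata against alignments", {
  ds <- tinyDataset()
  expect_silent(validateDataset(ds))
  # orphan sequence in alignment
  alns <- alignments(ds)
  extra <- c(as.character(sequences(alns$mtA)), ZZ_mt = "ACGTACGT")
  alns$mtA <- LocusAlignment("mtA", extra)
  expect_error(MultiLocusDataset(alns, samples(ds), registry(ds)),
               "no metadata owner")
})
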