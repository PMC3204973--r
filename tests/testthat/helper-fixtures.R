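# Small programmatic fixtures shared across test files.

mkAln <- function(..., marker = "toy") {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("h", seq_along(seqs))
  LocusAlignment(marker, seqs)
}

# A tiny two-cohort dataset built by hand: one mtDNA and one autosomal
# marker, 3 wild + 2 domestic individuals.
tinyDataset <- function() {
  reg <- MarkerRegistry(
    data.frame(name = c("nucA", "mtA"), chromosome = c("1", "MT"),
               inheritance = c("autosomal", "mtDNA"),
               length = c(12L, 8L),
               functional_class = c("functional_gene", "control_region")),
    coding = list(nucA = data.frame(start = 4L, end = 12L, frame = 1L,
                                    strand = "+")))
  nucSeqs <- c(
    W1_a = "AAACCCGGGTTT", W1_b = "AAACCCGGGTTT",
    W2_a = "AAACCCGGATTT", W2_b = "AAACCCGGGTTT",
    W3_a = "AAACCAGGGTTT", W3_b = "AAACCCGGGTTT",
    D1_a = "AAACCCGGGTTT", D1_b = "AAACCCGGGTTA",
    D2_a = "AAACCCGGGTTT", D2_b = "AAACCCGGGTTT")
  mtSeqs <- c(W1_mt = "ACGTACGT", W2_mt = "ACGTACGA", W3_mt = "ACGTACGT",
              D1_mt = "ACGTTCGT", D2_mt = "ACGTTCGT")
  smp <- data.frame(
    individual_id = c("W1", "W2", "W3", "D1", "D2"),
    cohort = c("wild", "wild", "wild", "domestic", "domestic"),
    group = c("NEA", "NEA", "SC", "SC", "Mekong"),
    population = c("NEA_site1", "NEA_site1", "SC_site1", "SC_breed1",
                   "Mekong_breed1"),
    nucA = c("W1_a,W1_b", "W2_a,W2_b", "W3_a,W3_b", "D1_a,D1_b", "D2_a,D2_b"),
    mtA = c("W1_mt", "W2_mt", "W3_mt", "D1_mt", "D2_mt"),
    stringsAsFactors = FALSE)
  MultiLocusDataset(list(LocusAlignment("nucA", nucSeqs),
                         LocusAlignment("mtA", mtSeqs)), smp, reg)
}

# quick scaled-down simulation config for unit tests
testConfig <- function(preset = "backcross", seed = 1, nLoci = 2,
                       wild = 6, dom = 8) {
  loci <- defaultLoci()
  loci <- rbind(loci[seq_len(nLoci), ], loci[15L, ])
  loci$length <- pmin(loci$length, 600L)
  scenarioConfig(preset, seed = seed, loci = loci,
                 samplesWild = wild, samplesDom = dom)
}
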