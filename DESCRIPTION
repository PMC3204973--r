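Package: mtnucdiv
Title: Contrasting Mitochondrial and Nuclear Genetic Diversity in Domestication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-locus population-genetic analysis of paired wild and domestic
    cohorts, designed around the mitochondrial/nuclear discordance that arises when
    a domestication bottleneck is followed by sex-biased backcrossing from the wild
    progenitor. Computes per-marker nucleotide diversity, Watterson's theta with a
    site-bootstrap interval, Tajima's D and Fu and Li's D* and F*, Hudson's F_ST,
    hierarchical AMOVA with permutation tests, pairwise-site linkage-disequilibrium
    scans by Fisher's exact test with Bonferroni correction, synonymous versus
    nonsynonymous mutation counts under nuclear and vertebrate-mitochondrial codes,
    per-SNP allele-frequency contrasts with the low-frequency allele-loss statistic,
    and median-joining haplotype networks. Includes a structured-coalescent
    simulator for the bottleneck-plus-backcross demography with sex-specific
    migration, and a rejection-ABC estimator of the sex bias in wild-to-domestic
    gene flow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
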