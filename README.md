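# mtnucdiv

Multi-locus population genetics of domestication: contrasting mitochondrial
and nuclear diversity between a domestic cohort and its wild progenitor.

## The problem

A domestication bottleneck should depress genetic diversity across the whole
genome — and more strongly in mtDNA, whose effective copy number is a quarter
of the autosomal one.  Yet East Asian pig surveys show the opposite
asymmetry: domestic pigs retain only about half of the wild-boar
mitochondrial diversity while their nuclear diversity is indistinguishable
from wild levels.  That discordance is the signature of **sex-biased
backcrossing**: recurrent matings between wild males and domestic females
replenish the nuclear gene pool after domestication but cannot touch the
maternally inherited mitochondrial pool.

`mtnucdiv` is a toolkit for detecting and modelling this signature in
phased multi-locus haplotype data.  It is aimed at population geneticists
working with marker panels of the classic resequencing design: one alignment
per locus, two haplotypes per individual at autosomal markers, one at mtDNA,
and cohort/region/population metadata.

## What it computes

Per marker and cohort (wild / domestic):

- nucleotide diversity **π = k/L**, Watterson's **θ_W = S/(a₁L)** with a
  site-bootstrap interval, **Tajima's D**, **Fu & Li's D\*, F\***
  (Simonsen-corrected variances), haplotype counts;
- **Hudson's F_ST = 1 − H_w/H_b** between cohorts and hierarchical
  **AMOVA** (Φ_CT, Φ_SC, Φ_ST with permutation tests) over
  groups/populations/sequences;
- pairwise-site **LD scans**: Fisher's exact test over all
  parsimony-informative site pairs with per-marker Bonferroni correction and
  the LD ratio P_s/P_T;
- codon-aware **N_A/N_S** counts under the standard or vertebrate
  mitochondrial code;
- per-SNP **allele-frequency contrasts** (chi-square) and the
  **low-frequency allele-loss** statistic (alleles under 10% frequency in
  the wild cohort absent from the domestic one);
- **median-joining haplotype networks** with deterministic tie-breaking;
- Evanno's **ΔK** post-processing of clustering likelihood tables;
- the effective migrant number **M_N = M·θ** and a **rejection-ABC**
  estimator of the posterior probability of male-biased gene flow,
  P(m_m > m_f | data).

A structured-coalescent simulator (`scenarioConfig()`, `simulateDataset()`)
generates study-shaped synthetic datasets under the
bottleneck-plus-backcross demography: two demes, a founder-phase size drop,
and backward migration of domestic lineages into the wild deme at the female
rate m_f for mtDNA and the sex-averaged rate (m_f+m_m)/2 for autosomes.

## Worked example

```r
library(mtnucdiv)

cfg <- scenarioConfig("backcross", seed = 3,
                      samplesWild = 5, samplesDom = 8,
                      loci = defaultLoci()[c(1, 15), ])
sim <- simulateDataset(cfg)
div <- diversitySummary(sim$dataset, nBoot = 10)
div[, c("marker", "cohort", "N", "S", "pi", "theta_w", "D")]
#>   marker   cohort  N  S          pi     theta_w            D
#> 1  nuc01     wild 10 27 0.004735329 0.004842271 -0.105539226
#> 2  nuc01 domestic 16 30 0.005162354 0.004586995  0.518880325
#> 3    mt1     wild  5 87 0.030500000 0.034800000 -0.938051735
#> 4    mt1 domestic  8 66 0.021190476 0.021212121 -0.005520417
```

Per-site diversity sits at the configured magnitudes (nuclear θ ≈ 0.005,
mtDNA control-region θ ≈ 0.026–0.035), and already in this toy run the
domestic cohort has lost mtDNA diversity (0.021 vs 0.031) while nuclear
diversity is undiminished (0.0052 vs 0.0047) — the backcross signature.
`runAnalysis()` produces the full report bundle (diversity, F_ST/Φ_CT,
N_A/N_S, LD, SNP table, AMOVA, headline retention percentages) as TSVs plus
a JSON manifest:

```r
rep <- runAnalysis(sim$dataset, outDir = "report", nBoot = 20,
                   nPerm = 50, seed = 2)
rep$headline$mt_retention_percent         # e.g. 61.0
rep$headline$autosomal_retention_percent  # e.g. 94.7
```

A thin command-line front end with `simulate` / `analyze` / `abc` /
`deltak` / `validate` subcommands is installed at
`inst/scripts/mtnucdiv-cli.R`.

## Package layout

- `R/` — S4 classes (`LocusAlignment`, `MarkerRegistry`,
  `MultiLocusDataset`, `SimConfig`, `AmovaResult`, `HaploNetwork`,
  `AbcPosterior`) and the analysis modules;
- `inst/extdata/nuclear_markers_registry.dcf` — a 14-marker registry fixture
  (real panel lengths; placeholder interval positions);
- `vignettes/mtnucdiv-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, simulator calibration, limitations;
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (hypergeometric enumeration, hand-solved AMOVA,
  dual-transcription neutrality statistics).
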