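# Orchestration: run the full multi-locus analysis on a dataset directory or
# object and emit the report bundle.

#' Percentage of diversity retained in the domestic cohort
#'
#' `100 * thetaDom / thetaWild`, the headline retention statistic (e.g. the
#' fraction of wild mtDNA diversity surviving domestication).
#'
#' @param thetaDom,thetaWild scaled-diversity estimates of the two cohorts.
#' @return percentage; `NA` when `thetaWild` is 0.
#' @export
retentionPercent <- function(thetaDom, thetaWild) {
  stopifnot(thetaDom >= 0, thetaWild >= 0)
  if (thetaWild == 0) return(NA_real_)
  100 * thetaDom / thetaWild
}

.fmt <- function(x, digits = 2L) ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the complete multi-locus analysis
#'
#' Produces the full report bundle for a dataset: the per-marker diversity
#' summary (with wild/domestic rows, Hudson's F_ST and the two-cohort
#' Phi_CT), the N_A/N_S tables for mtDNA and nuclear coding markers, the LD
#' scan table, the per-SNP frequency table, the hierarchical AMOVA tables,
#' and a headline block (mtDNA/autosomal diversity retention, low-frequency
#' allele loss, significant-SNP fraction).  Display columns follow the
#' conventional scaling -- pi and theta multiplied by 10^3, F_ST and Phi_CT
#' by 10^2, ratios as percentages to 2 decimals -- while the unscaled
#' machine columns are retained alongside.
#'
#' @param dataset a [MultiLocusDataset-class] or a dataset directory path.
#' @param outDir output directory for the report TSVs and the JSON manifest
#'   (`NULL` to skip writing).
#' @param nBoot bootstrap resamples for the theta interval.
#' @param nPerm AMOVA permutations.
#' @param ldAlpha family-wise level of the LD scan.
#' @param lowFreqThreshold wild-frequency cutoff of the allele-loss
#'   statistic (0.10 by default; 0.05 is the common alternative).
#' @param fisherFallback Fisher fallback for sparse SNP tables (off by
#'   default).
#' @param seed integer seed for every stochastic step.
#' @param verbose print per-stage progress.
#' @return invisibly, a list with elements `diversity`, `fst`, `codingMt`,
#'   `codingNuclear`, `ld`, `snp`, `amova`, `headline`, `manifest`.
#' @export
runAnalysis <- function(dataset, outDir = NULL, nBoot = 200L, nPerm = 200L,
                        ldAlpha = 0.05, lowFreqThreshold = 0.10,
                        fisherFallback = FALSE, seed = 1L, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)
  if (is.character(dataset)) dataset <- readDataset(dataset)
  validateDataset(dataset)
  reg <- registryTable(registry(dataset))
  smp <- samples(dataset)

  say("diversity statistics")
  div <- diversitySummary(dataset, nBoot = nBoot, seed = seed)
  div$pi_x1000 <- round(1000 * div$pi, 2)
  div$theta_x1000 <- round(1000 * div$theta_w, 2)

  say("differentiation (F_ST, AMOVA)")
  fstRows <- list(); amovaRows <- list()
  for (m in names(alignments(dataset))) {
    aln <- alignments(dataset)[[m]]
    wild <- cohortSlice(aln, smp, "wild")
    dom <- cohortSlice(aln, smp, "domestic")
    if (nSequences(wild) < 2L || nSequences(dom) < 2L) next
    pooled <- methods::new("LocusAlignment", marker = m,
                           seqs = c(sequences(wild), sequences(dom)))
    lab <- c(rep("wild", nSequences(wild)), rep("domestic", nSequences(dom)))
    fst <- hudsonFst(pooled, lab)
    # two-level design: cohorts are the groups, populations nested inside
    owner <- .sequenceOwners(pooled, smp, m)
    part <- data.frame(group = smp$cohort[owner], population = smp$population[owner])
    am <- amova(pooled, part, nPerm = nPerm, seed = seed)
    fstRows[[m]] <- data.frame(marker = m, fst = fst,
                               fst_x100 = round(100 * fst, 2),
                               phi_ct = unname(am@phi["phi_CT"]),
                               phi_ct_x100 = round(100 * am@phi["phi_CT"], 2),
                               phi_ct_p = unname(am@pValues["phi_CT"]))
    amovaRows[[m]] <- data.frame(
      marker = m, scheme = "cohort_2level",
      sigma2_among_groups = am@components[1L],
      sigma2_among_pops = am@components[2L],
      sigma2_within_pops = am@components[3L],
      pct_among_groups = 100 * am@components[1L] / sum(am@components),
      phi_ct = am@phi[["phi_CT"]], phi_sc = am@phi[["phi_SC"]],
      phi_st = am@phi[["phi_ST"]], p_ct = am@pValues[["phi_CT"]],
      p_sc = am@pValues[["phi_SC"]], p_st = am@pValues[["phi_ST"]])
  }
  fstTab <- do.call(rbind, fstRows)
  amovaTab <- do.call(rbind, amovaRows)

  say("LD scan")
  ldRows <- list()
  for (m in names(alignments(dataset))) {
    for (ch in COHORT_LEVELS) {
      aln <- cohortSlice(alignments(dataset)[[m]], smp, ch)
      if (nSequences(aln) < 2L) next
      sc <- ldScan(aln, alpha = ldAlpha)
      ldRows[[paste(m, ch)]] <- data.frame(
        marker = m, cohort = ch, Ps = sc$Ps, PT = sc$PT, ratio = sc$ratio,
        ratio_pct = .fmt(sc$ratio), alpha_effective = sc$alphaEffective)
    }
  }
  ldTab <- do.call(rbind, ldRows)

  say("coding N_A/N_S")
  codingMarkers <- reg$name[vapply(reg$name, function(m)
    nrow(codingIntervals(registry(dataset), m)) > 0L, logical(1))]
  mtCoding <- intersect(codingMarkers, reg$name[reg$inheritance == "mtDNA"])
  nucCoding <- setdiff(codingMarkers, mtCoding)
  codingMt <- if (length(mtCoding))
    rbind(codingCountsTable(dataset, "wild", mtCoding),
          codingCountsTable(dataset, "domestic", mtCoding)) else NULL
  codingNuc <- if (length(nucCoding))
    rbind(codingCountsTable(dataset, "wild", nucCoding),
          codingCountsTable(dataset, "domestic", nucCoding)) else NULL

  say("SNP frequency table")
  snp <- snpTable(dataset, fisherFallback = fisherFallback)
  loss <- lowFreqLoss(snp, threshold = lowFreqThreshold)

  say("headline quantities")
  agg <- function(mode, cohort, col) {
    mk <- reg$name[reg$inheritance == mode]
    mean(div[[col]][div$marker %in% mk & div$cohort == cohort], na.rm = TRUE)
  }
  headline <- list(
    mt_retention_percent = retentionPercent(agg("mtDNA", "domestic", "theta_w"),
                                            agg("mtDNA", "wild", "theta_w")),
    autosomal_retention_percent = retentionPercent(
      agg("autosomal", "domestic", "theta_w"), agg("autosomal", "wild", "theta_w")),
    mt_pi_ratio = agg("mtDNA", "domestic", "pi") / agg("mtDNA", "wild", "pi"),
    autosomal_pi_ratio = agg("autosomal", "domestic", "pi") /
      agg("autosomal", "wild", "pi"),
    low_freq_loss_percent = loss$lossPercent,
    n_wild_low_freq_alleles = loss$nWildLow,
    n_retained_in_domestic = loss$nRetained,
    significant_snp_percent = if (nrow(snp)) significantSnpPercent(snp) else NA_real_)

  manifest <- list(package = "mtnucdiv",
                   version = as.character(packageVersion("mtnucdiv")),
                   seed = seed, nBoot = nBoot, nPerm = nPerm,
                   ldAlpha = ldAlpha, lowFreqThreshold = lowFreqThreshold,
                   fisherFallback = fisherFallback,
                   nMarkers = nrow(reg), nIndividuals = nrow(smp),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  out <- list(diversity = div, fst = fstTab, codingMt = codingMt,
              codingNuclear = codingNuc, ld = ldTab, snp = snp,
              amova = amovaTab, headline = headline, manifest = manifest)

  if (!is.null(outDir)) {
    ok <- FALSE
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character()
    on.exit(if (!ok) unlink(written), add = TRUE)
    wt <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      written <<- c(written, .writeTsv(df, file.path(outDir, name)))
    }
    wt(div, "diversity_summary.tsv")
    wt(fstTab, "fst_phi.tsv")
    wt(codingMt, "na_ns_mtdna.tsv")
    wt(codingNuc, "na_ns_nuclear.tsv")
    wt(ldTab, "ld_ratios.tsv")
    wt(snp, "snp_frequencies.tsv")
    wt(amovaTab, "amova.tsv")
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(c(manifest, list(headline = headline)), manifestPath,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, manifestPath)
    ok <- TRUE
  }
  say("done")
  invisible(out)
}

# map each sequence of a pooled alignment back to its owning sample row
.sequenceOwners <- function(alignment, samples, m) {
  ids <- names(sequences(alignment))
  ownerOf <- rep(NA_integer_, length(ids))
  for (r in seq_len(nrow(samples))) {
    hit <- ids %in% .parseHapIds(samples[[m]][r])
    ownerOf[hit] <- r
  }
  if (anyNA(ownerOf))
    stop("validation error: sequence with no metadata owner at marker '", m, "'")
  ownerOf
}
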