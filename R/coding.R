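# Codon-aware classification of observed mutations as synonymous or
# nonsynonymous.

.geneticCode <- function(code = c("standard", "vertebrate_mitochondrial")) {
  code <- match.arg(code)
  if (code == "standard") Biostrings::GENETIC_CODE
  else Biostrings::getGeneticCode("SGC1")
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a point mutation as synonymous or nonsynonymous
#'
#' Substitutes `altBase` at `positionInCodon` of `refCodon` and compares the
#' encoded amino acids under the requested genetic code (standard nuclear or
#' vertebrate mitochondrial, where e.g. ATA encodes Met rather than Ile).
#'
#' @param refCodon reference codon (3 letters, gap-free).
#' @param positionInCodon 1, 2 or 3.
#' @param altBase the alternative base.
#' @param code `"standard"` or `"vertebrate_mitochondrial"`.
#' @return `"synonymous"` or `"nonsynonymous"`; `NA_character_` with a
#'   warning when the codon involves `N` or `-`.
#' @examples
#' classifyMutation("GGA", 3, "G")                               # synonymous
#' classifyMutation("ATA", 3, "G", "vertebrate_mitochondrial")   # Met -> Met
#' @export
classifyMutation <- function(refCodon, positionInCodon, altBase,
                             code = c("standard", "vertebrate_mitochondrial")) {
  refCodon <- toupper(refCodon); altBase <- toupper(altBase)
  stopifnot(nchar(refCodon) == 3L, positionInCodon %in% 1:3)
  if (grepl("[^ACGT]", refCodon) || !altBase %in% BASES) {
    warning("codon '", refCodon, "' / allele '", altBase,
            "' contains missing data; classification skipped")
    return(NA_character_)
  }
  gc <- .geneticCode(code)
  alt <- refCodon
  substr(alt, positionInCodon, positionInCodon) <- altBase
  if (gc[[refCodon]] == gc[[alt]]) "synonymous" else "nonsynonymous"
}

#' N_A/N_S ratio from raw counts
#'
#' @param nA nonsynonymous mutation count.
#' @param nS synonymous mutation count.
#' @return `nA / nS`, or `NA_real_` when `nS == 0` (the ratio is reported as
#'   not available, never as infinity).
#' @export
naNsRatio <- function(nA, nS) {
  stopifnot(nA >= 0, nS >= 0)
  if (nS == 0) return(NA_real_)
  nA / nS
}

# reading-order positions and (complemented) base accessor for an interval
.readingFrameSites <- function(iv) {
  pos <- if (iv$strand == "+") iv$start:iv$end else iv$end:iv$start
  codonPos <- ((iv$frame - 1L + seq_along(pos) - 1L) %% 3L) + 1L
  data.frame(column = pos, codon_pos = codonPos,
             codon_id = cumsum(codonPos == 1L) + (codonPos[1L] != 1L))
}

#' Count synonymous and nonsynonymous mutations in one cohort at one marker
#'
#' Walks the marker's coding intervals (1-based closed coordinates; minus-
#' strand intervals are read on the reverse complement, with `frame` giving
#' the codon position of the first base in reading direction).  Every
#' segregating coding site contributes one classification per non-major
#' allele, evaluated in the codon whose other positions carry the cohort's
#' major alleles -- a deterministic, order-independent context for
#' multi-variant codons.  Columns containing `-` or `N`, and codons truncated
#' at interval edges, are skipped (counted in `nSkipped`).
#'
#' The genetic code follows the marker's inheritance mode: standard for
#' autosomal markers, vertebrate mitochondrial for mtDNA markers.
#'
#' @param alignment one cohort's [LocusAlignment-class].
#' @param registry the [MarkerRegistry-class] carrying the coding intervals.
#' @param cohort cohort label recorded in the output.
#' @return list of class `CodingCounts`: `marker`, `cohort`, `nA`, `nS`,
#'   `ratio` (`NA` when `nS == 0`), `nSkipped`.
#' @export
naNsTable <- function(alignment, registry, cohort = NA_character_) {
  mName <- marker(alignment)
  iv <- codingIntervals(registry, mName)
  tb <- registryTable(registry)
  code <- if (tb$inheritance[match(mName, tb$name)] == "mtDNA")
    "vertebrate_mitochondrial" else "standard"
  gc <- .geneticCode(code)
  m <- .alnMatrix(alignment)
  nA <- 0L; nS <- 0L; skipped <- 0L
  for (r in seq_len(nrow(iv))) {
    sites <- .readingFrameSites(iv[r, ])
    minus <- iv$strand[r] == "-"
    # major allele per column in reading orientation; NA when column has -/N
    majors <- vapply(sites$column, function(col) {
      colv <- m[, col]
      if (any(colv == "-" | colv == "N")) return(NA_character_)
      cnt <- table(factor(colv, levels = BASES))
      BASES[which.max(cnt)]
    }, "")
    if (minus) majors <- unname(.COMPLEMENT[majors])
    for (ci in unique(sites$codon_id)) {
      ix <- which(sites$codon_id == ci)
      if (length(ix) != 3L) { # codon truncated at an interval edge
        seg <- vapply(sites$column[ix], function(col) {
          colv <- m[, col]
          !any(colv == "-" | colv == "N") && length(unique(colv)) > 1L
        }, logical(1))
        skipped <- skipped + sum(seg)
        next
      }
      if (anyNA(majors[ix])) {
        skipped <- skipped + sum(!is.na(majors[ix]) & vapply(
          sites$column[ix], function(col) length(unique(m[, col])) > 1L,
          logical(1)))
        next
      }
      refCodon <- paste(majors[ix], collapse = "")
      for (k in 1:3) {
        col <- sites$column[ix[k]]
        colv <- m[, col]
        alleles <- setdiff(unique(colv), c("-", "N"))
        obsMajor <- if (minus) .COMPLEMENT[[majors[ix[k]]]] else majors[ix[k]]
        for (al in setdiff(alleles, obsMajor)) {
          alt <- if (minus) .COMPLEMENT[[al]] else al
          cls <- gc[[`substr<-`(refCodon, k, k, alt)]] == gc[[refCodon]]
          if (cls) nS <- nS + 1L else nA <- nA + 1L
        }
      }
    }
  }
  out <- list(marker = mName, cohort = cohort, nA = nA, nS = nS,
              ratio = naNsRatio(nA, nS), nSkipped = skipped)
  class(out) <- "CodingCounts"
  out
}

#' @export
print.CodingCounts <- function(x, ...) {
  cat(sprintf("CodingCounts '%s' (%s): N_A=%d, N_S=%d, N_A/N_S=%s\n",
              x$marker, x$cohort, x$nA, x$nS,
              if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Per-marker N_A/N_S table for a cohort, with a totals row
#'
#' @param dataset a [MultiLocusDataset-class].
#' @param cohort `"wild"` or `"domestic"`.
#' @param markers markers to include (default: all with coding intervals).
#' @return data.frame with one row per marker plus a `Total` row; the `ratio`
#'   column is `NA` where `nS == 0`.
#' @export
codingCountsTable <- function(dataset, cohort, markers = NULL) {
  reg <- registry(dataset)
  if (is.null(markers))
    markers <- registryTable(reg)$name[vapply(registryTable(reg)$name,
      function(m) nrow(codingIntervals(reg, m)) > 0L, logical(1))]
  rows <- lapply(markers, function(m) {
    cc <- naNsTable(cohortSlice(alignments(dataset)[[m]], samples(dataset),
                                cohort), reg, cohort)
    data.frame(marker = m, cohort = cohort, nA = cc$nA, nS = cc$nS,
               ratio = cc$ratio)
  })
  tab <- do.call(rbind, rows)
  tot <- data.frame(marker = "Total", cohort = cohort, nA = sum(tab$nA),
                    nS = sum(tab$nS), ratio = naNsRatio(sum(tab$nA), sum(tab$nS)))
  rbind(tab, tot)
}
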