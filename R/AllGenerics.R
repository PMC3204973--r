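# Generics and accessors.

#' @rdname LocusAlignment-class
#' @param x a `LocusAlignment` (or, for `alignments`/`samples`/`registry`, a
#'   `MultiLocusDataset`).
#' @export
setGeneric("marker", function(x) standardGeneric("marker"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname LocusAlignment-class
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname MultiLocusDataset-class
#' @param x object.
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname MultiLocusDataset-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname MultiLocusDataset-class
#' @export
setGeneric("registry", function(x) standardGeneric("registry"))

#' @rdname MarkerRegistry-class
#' @param x a `MarkerRegistry`.
#' @export
setGeneric("registryTable", function(x) standardGeneric("registryTable"))

#' @rdname MarkerRegistry-class
#' @param marker marker name.
#' @export
setGeneric("codingIntervals", function(x, marker) standardGeneric("codingIntervals"))

#' @rdname MarkerRegistry-class
#' @export
setGeneric("registryTotals", function(x) standardGeneric("registryTotals"))

setMethod("marker", "LocusAlignment", function(x) x@marker)
setMethod("sequences", "LocusAlignment", function(x) x@seqs)
setMethod("nSequences", "LocusAlignment", function(x) length(x@seqs))
setMethod("alignmentLength", "LocusAlignment", function(x)
  if (length(x@seqs)) Biostrings::width(x@seqs)[1L] else 0L)

setMethod("alignments", "MultiLocusDataset", function(x) x@alignments)
setMethod("samples", "MultiLocusDataset", function(x) x@samples)
setMethod("registry", "MultiLocusDataset", function(x) x@registry)

setMethod("registryTable", "MarkerRegistry", function(x) x@table)
setMethod("codingIntervals", "MarkerRegistry", function(x, marker) {
  if (!marker %in% x@table$name)
    stop("unknown marker: ", marker)
  x@coding[[marker]]
})

#' @describeIn MarkerRegistry-class total, coding and noncoding base-pair
#'   counts summed over the registry (named numeric of length 3).
setMethod("registryTotals", "MarkerRegistry", function(x) {
  coding <- vapply(x@coding, function(iv)
    if (nrow(iv)) sum(iv$end - iv$start + 1L) else 0L, integer(1))
  coding <- sum(coding[x@table$name])
  total <- sum(x@table$length)
  c(total_bp = total, coding_bp = coding, noncoding_bp = total - coding)
})

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment '", object@marker, "': ", length(object@seqs),
      " sequences of length ", alignmentLength(object), " bp\n", sep = "")
})

setMethod("show", "MarkerRegistry", function(object) {
  tot <- registryTotals(object)
  cat("MarkerRegistry with ", nrow(object@table), " markers (",
      tot["total_bp"], " bp; coding ", tot["coding_bp"], " bp)\n", sep = "")
  print(utils::head(object@table, 8L), row.names = FALSE)
  if (nrow(object@table) > 8L) cat("...\n")
})

setMethod("show", "MultiLocusDataset", function(object) {
  cat("MultiLocusDataset: ", length(object@alignments), " markers, ",
      nrow(object@samples), " individuals (",
      sum(object@samples$cohort == "wild"), " wild, ",
      sum(object@samples$cohort == "domestic"), " domestic)\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: N_wild=", object@nWild, ", N_dom=", object@nDom,
      ", founder=", object@founderSize, ", T_dom=", object@tDom,
      ", T_bottleneck=", object@tBottleneck, "\n  m_f=", object@mF,
      ", m_m=", object@mM, ", mu_nuc=", object@muNuclear,
      ", mu_mt=", object@muMt, "\n  ", nrow(object@loci), " loci; samples ",
      object@samplesWild, " wild + ", object@samplesDom,
      " domestic individuals; seed ", object@seed, "\n", sep = "")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA (", object@nPermutations, " permutations)\n", sep = "")
  tot <- sum(object@components)
  tab <- data.frame(
    stratum = c("among groups", "among pops within groups", "within pops"),
    df = object@df, SSD = object@ssd, sigma2 = object@components,
    pct = if (isTRUE(tot > 0)) 100 * object@components / tot else NA_real_)
  print(tab, row.names = FALSE, digits = 4)
  phi <- object@phi; p <- object@pValues
  cat(sprintf("Phi_CT = %s (p = %s), Phi_SC = %s (p = %s), Phi_ST = %s (p = %s)\n",
              format(phi[["phi_CT"]], digits = 4), format(p[["phi_CT"]], digits = 3),
              format(phi[["phi_SC"]], digits = 4), format(p[["phi_SC"]], digits = 3),
              format(phi[["phi_ST"]], digits = 4), format(p[["phi_ST"]], digits = 3)))
})

setMethod("show", "HaploNetwork", function(object) {
  cat("HaploNetwork: ", sum(!object@nodes$median), " observed haplotypes, ",
      sum(object@nodes$median), " median vectors, ", nrow(object@edges),
      " edges\n", sep = "")
})

setMethod("show", "AbcPosterior", function(object) {
  cat("AbcPosterior: ", nrow(object@draws), " accepted of ", object@nSims,
      " simulations (", 100 * object@acceptFraction, "%)\n",
      "P(m_m > m_f | data) = ", format(object@pMaleBiased, digits = 3), "\n",
      sep = "")
  if (length(object@dropped))
    cat("dropped zero-variance summaries: ",
        paste(object@dropped, collapse = ", "), "\n", sep = "")
})
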