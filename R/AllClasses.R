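# S4 class definitions for the package's central data containers.

#' One marker's phased haplotype alignment
#'
#' A `LocusAlignment` holds the phased haplotype sequences of a single marker
#' as a [Biostrings::DNAStringSet].  All sequences must have identical width
#' (the input is assumed pre-aligned), carry unique ids, and use only the
#' characters `A`, `C`, `G`, `T`, `-` (alignment gap) and `N` (missing).
#'
#' @slot marker single marker name.
#' @slot seqs a `DNAStringSet` of equal-width sequences, named by sequence id.
#'
#' @seealso [readLocusAlignment()], [cohortSlice()], [siteCounts()]
#' @exportClass LocusAlignment
setClass("LocusAlignment",
         representation(marker = "character", seqs = "DNAStringSet"))

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@marker) != 1L || is.na(object@marker) || !nzchar(object@marker))
    msg <- c(msg, "'marker' must be a single non-empty string")
  w <- Biostrings::width(object@seqs)
  if (length(w) > 0L) {
    if (length(unique(w)) != 1L)
      msg <- c(msg, "all sequences must have the same length")
    else if (w[1L] < 1L)
      msg <- c(msg, "alignment length must be >= 1")
    ids <- names(object@seqs)
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all sequences must be named")
    else if (anyDuplicated(ids))
      msg <- c(msg, paste0("duplicated sequence ids: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Marker registry: per-locus metadata
#'
#' Mirrors a marker summary table: one row per locus with its chromosome,
#' inheritance mode (`autosomal` or `mtDNA`), aligned length, functional class
#' and, for coding markers, the coding intervals in 1-based closed coordinates
#' on the alignment, each with a reading frame (codon position of the first
#' base in reading direction, 1--3) and strand.
#'
#' @slot table data.frame with columns `name`, `chromosome`, `inheritance`,
#'   `length`, `functional_class`.
#' @slot coding named list (one element per marker) of data.frames with
#'   columns `start`, `end`, `frame`, `strand`; zero-row for noncoding markers.
#'
#' @seealso [readMarkerRegistry()], [registryTotals()], [naNsTable()]
#' @exportClass MarkerRegistry
setClass("MarkerRegistry",
         representation(table = "data.frame", coding = "list"))

setValidity("MarkerRegistry", function(object) {
  tb <- object@table
  need <- c("name", "chromosome", "inheritance", "length", "functional_class")
  if (!all(need %in% names(tb)))
    return(paste0("registry table must have columns: ", paste(need, collapse = ", ")))
  msg <- character()
  if (anyDuplicated(tb$name))
    msg <- c(msg, "duplicated marker names in registry")
  if (!all(tb$inheritance %in% c("autosomal", "mtDNA")))
    msg <- c(msg, "inheritance must be 'autosomal' or 'mtDNA'")
  if (!all(tb$functional_class %in% FUNCTIONAL_CLASSES))
    msg <- c(msg, paste0("functional_class must be one of: ",
                         paste(FUNCTIONAL_CLASSES, collapse = ", ")))
  if (any(tb$length < 1L))
    msg <- c(msg, "marker length must be >= 1")
  if (!setequal(names(object@coding), tb$name))
    msg <- c(msg, "coding list must have one element per registry marker")
  for (nm in names(object@coding)) {
    iv <- object@coding[[nm]]
    if (nrow(iv) == 0L) next
    len <- tb$length[match(nm, tb$name)]
    if (any(iv$start < 1L) || any(iv$end > len) || any(iv$end < iv$start))
      msg <- c(msg, paste0(nm, ": coding interval outside 1..length"))
    if (!all(iv$frame %in% 1:3))
      msg <- c(msg, paste0(nm, ": frame must be 1, 2 or 3"))
    if (!all(iv$strand %in% c("+", "-")))
      msg <- c(msg, paste0(nm, ": strand must be '+' or '-'"))
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)]))
      msg <- c(msg, paste0(nm, ": overlapping coding intervals"))
    if (sum(iv$end - iv$start + 1L) > len)
      msg <- c(msg, paste0(nm, ": coding intervals exceed marker length"))
  }
  if (length(msg)) msg else TRUE
})

#' A complete multi-locus dataset
#'
#' Bundles the per-marker alignments, the sample metadata table and the marker
#' registry.  The sample table has one row per individual with columns
#' `individual_id`, `cohort` (`wild`/`domestic`), `group` (one of the seven
#' region codes), `population` (breed or sampling site), and one column per
#' marker holding the comma-separated haplotype ids of that individual (one id
#' for mtDNA markers, two for autosomal markers).
#'
#' @slot alignments named list of [LocusAlignment] objects.
#' @slot samples the sample metadata data.frame.
#' @slot registry a [MarkerRegistry].
#'
#' @seealso [readDataset()], [validateDataset()], [runAnalysis()]
#' @exportClass MultiLocusDataset
setClass("MultiLocusDataset",
         representation(alignments = "list", samples = "data.frame",
                        registry = "MarkerRegistry"))

#' Demographic configuration for the bottleneck + backcross coalescent
#'
#' Parameters of the two-deme structured coalescent: a wild deme of constant
#' diploid size and a domestic deme founded `tDom` generations ago, whose size
#' drops to `founderSize` during the founding phase (the `tBottleneck`
#' generations immediately after domestication).  Backward in time, domestic
#' lineages migrate into the wild deme at the female rate `mF` (mtDNA) or the
#' sex-averaged rate `(mF + mM)/2` (autosomes); at `tDom` the domestic deme
#' merges into the wild deme.  Mutations follow the infinite-sites model.
#'
#' @slot nWild,nDom diploid effective sizes of the two demes.
#' @slot founderSize diploid size of the domestic deme during the founding phase.
#' @slot tDom generations since domestication.
#' @slot tBottleneck duration of the founding phase (generations, `<= tDom`).
#' @slot mF,mM per-generation backward migration probabilities of a domestic
#'   lineage tracing to a wild mother (`mF`) or father (`mM`).
#' @slot muNuclear,muMt per-site per-generation mutation rates.
#' @slot femaleFraction fraction of females; the mtDNA copy number of a deme of
#'   diploid size N is `femaleFraction * N`.
#' @slot loci data.frame (`name`, `length`, `inheritance`, `functional_class`).
#' @slot samplesWild,samplesDom numbers of sampled individuals per cohort.
#' @slot seed integer seed driving all randomness.
#'
#' @seealso [scenarioConfig()], [simulateLocus()], [simulateDataset()]
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nWild = "numeric", nDom = "numeric",
                        founderSize = "numeric", tDom = "numeric",
                        tBottleneck = "numeric", mF = "numeric", mM = "numeric",
                        muNuclear = "numeric", muMt = "numeric",
                        femaleFraction = "numeric", loci = "data.frame",
                        samplesWild = "numeric", samplesDom = "numeric",
                        seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(c(object@nWild, object@nDom, object@founderSize) < 1))
    msg <- c(msg, "population sizes must be >= 1")
  if (object@mF < 0 || object@mF > 1 || object@mM < 0 || object@mM > 1)
    msg <- c(msg, "migration rates must lie in [0, 1]")
  if (object@tBottleneck > object@tDom || object@tBottleneck < 0)
    msg <- c(msg, "need 0 <= tBottleneck <= tDom")
  if (object@muNuclear < 0 || object@muMt < 0)
    msg <- c(msg, "mutation rates must be >= 0")
  if (object@femaleFraction <= 0 || object@femaleFraction >= 1)
    msg <- c(msg, "femaleFraction must lie in (0, 1)")
  need <- c("name", "length", "inheritance", "functional_class")
  if (!all(need %in% names(object@loci)))
    msg <- c(msg, "loci must have columns name, length, inheritance, functional_class")
  if (object@samplesWild < 0 || object@samplesDom < 0)
    msg <- c(msg, "sample sizes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hierarchical AMOVA result
#'
#' Method-of-moments variance components for the three-level hierarchy
#' (groups / populations within groups / sequences within populations) of
#' squared molecular distances, with the Phi fixation indices and their
#' permutation p-values.  Components other than the within-population one may
#' be negative, as is usual for moment estimators.
#'
#' @slot components named numeric: `sigma2_among_groups`,
#'   `sigma2_among_pops_within_groups`, `sigma2_within_pops`.
#' @slot phi named numeric: `phi_CT`, `phi_SC`, `phi_ST` (NA when undefined).
#' @slot pValues permutation p-values for the Phi statistics.
#' @slot nPermutations number of permutations used.
#' @slot ssd,df sums of squared deviations and degrees of freedom per stratum.
#'
#' @seealso [amova()]
#' @exportClass AmovaResult
setClass("AmovaResult",
         representation(components = "numeric", phi = "numeric",
                        pValues = "numeric", nPermutations = "numeric",
                        ssd = "numeric", df = "numeric"))

setValidity("AmovaResult", function(object) {
  msg <- character()
  if (any(object@phi > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "Phi statistics cannot exceed 1")
  if (!is.na(object@components["sigma2_within_pops"]) &&
      object@components["sigma2_within_pops"] < -1e-12)
    msg <- c(msg, "within-population variance component must be >= 0")
  p <- object@pValues
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Median-joining haplotype network
#'
#' Nodes are observed haplotypes (with their sample frequencies and, when
#' supplied, per-region composition) plus inferred median vectors (frequency
#' 0); edges carry the number of mutations separating their endpoints.
#'
#' @slot nodes data.frame with columns `id`, `haplotype`, `frequency`,
#'   `median` (logical), plus optional composition columns.
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @slot connected logical: is the network connected (always TRUE for
#'   nonempty input).
#'
#' @seealso [medianJoining()]
#' @exportClass HaploNetwork
setClass("HaploNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        connected = "logical"))

#' Rejection-ABC posterior for sex-biased migration
#'
#' Accepted draws of `(mF, mM, founderSize)` from a rejection sampler that
#' matches simulated to observed summary statistics in standardized Euclidean
#' distance.
#'
#' @slot draws data.frame of accepted draws (columns `mF`, `mM`,
#'   `founderSize`, `distance`).
#' @slot acceptFraction fraction of simulations accepted.
#' @slot nSims number of prior draws simulated.
#' @slot priors the prior specification (list of ranges).
#' @slot pMaleBiased posterior probability that `mM > mF`.
#' @slot dropped names of summaries dropped for zero prior-predictive variance.
#'
#' @seealso [abcSexBias()]
#' @exportClass AbcPosterior
setClass("AbcPosterior",
         representation(draws = "data.frame", acceptFraction = "numeric",
                        nSims = "numeric", priors = "list",
                        pMaleBiased = "numeric", dropped = "character"))
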