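# Reading, writing and validating alignments, sample metadata and the
# marker registry.

ALLOWED_CHARS <- c("A", "C", "G", "T", "-", "N")

#' Construct a LocusAlignment
#'
#' @param marker marker name.
#' @param seqs named character vector of aligned sequences, or a
#'   `DNAStringSet`.  Lower-case input is upper-cased.
#' @return a [LocusAlignment-class] object.
#' @examples
#' LocusAlignment("toy", c(h1 = "ACGT", h2 = "ACGA"))
#' @export
LocusAlignment <- function(marker, seqs) {
  if (is.character(seqs)) {
    seqs <- toupper(seqs)
    bad <- grepl("[^ACGTN-]", seqs)
    if (any(bad))
      stop("alignment-format error in marker '", marker, "': sequence ",
           paste(names(seqs)[bad], collapse = ", "),
           " contains characters outside {A,C,G,T,-,N}")
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
      off <- names(seqs)[w != w[1L]][1L]
      stop("alignment-format error in marker '", marker, "': record '", off,
           "' has length ", nchar(seqs[[off]]), " but expected ", w[1L])
    }
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  w <- Biostrings::width(seqs)
  if (length(w) && length(unique(w)) > 1L) {
    off <- names(seqs)[w != w[1L]][1L]
    stop("alignment-format error in marker '", marker, "': record '", off,
         "' has length ", w[w != w[1L]][1L], " but expected ", w[1L])
  }
  methods::new("LocusAlignment", marker = marker, seqs = seqs)
}

#' Read one marker's alignment from a FASTA file
#'
#' Sequences are upper-cased; records must be pre-aligned (equal length) and
#' restricted to the characters `A`, `C`, `G`, `T`, `-`, `N`.
#'
#' @param path FASTA file.
#' @param marker marker name to attach; defaults to the file name without
#'   extension.
#' @return a [LocusAlignment-class].
#' @export
readLocusAlignment <- function(path, marker = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("input error: FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(raw))  # keep the id token only
  seqs <- setNames(toupper(as.character(raw)), ids)
  LocusAlignment(marker, seqs)
}

#' Write a LocusAlignment to FASTA
#'
#' @param x a [LocusAlignment-class].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeLocusAlignment <- function(x, path, width = 70L) {
  Biostrings::writeXStringSet(x@seqs, path, width = width)
  invisible(path)
}

.parseHapIds <- function(s) {
  s <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  s[nzchar(s)]
}

#' Read the sample metadata table
#'
#' The TSV has columns `individual_id`, `cohort`, `group`, `population`, then
#' one column per marker holding that individual's haplotype ids
#' (comma-separated; one id for mtDNA markers, two for autosomal markers --
#' the two may name identical haplotype sequences but must be distinct ids).
#'
#' @param path TSV file.
#' @param registry optional [MarkerRegistry-class]; when given, the per-marker
#'   haplotype-id counts are checked against the marker's inheritance mode.
#' @return the validated data.frame.
#' @export
readSampleTable <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  tb <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  validateSampleTable(tb, registry)
}

#' @rdname readSampleTable
#' @param samples a sample metadata data.frame to validate in place.
#' @export
validateSampleTable <- function(samples, registry = NULL) {
  need <- c("individual_id", "cohort", "group", "population")
  if (!all(need %in% names(samples)))
    stop("input error: sample table must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(samples$individual_id))
    stop("input error: duplicated individual_id in sample table")
  if (!all(samples$cohort %in% COHORT_LEVELS))
    stop("input error: cohort must be 'wild' or 'domestic'; offending value: ",
         paste(setdiff(unique(samples$cohort), COHORT_LEVELS), collapse = ", "))
  if (!all(samples$group %in% REGION_CODES))
    stop("input error: unknown group code: ",
         paste(setdiff(unique(samples$group), REGION_CODES), collapse = ", "),
         " (expected one of ", paste(REGION_CODES, collapse = ", "), ")")
  mcols <- setdiff(names(samples), need)
  if (!is.null(registry)) {
    tb <- registryTable(registry)
    for (m in intersect(mcols, tb$name)) {
      want <- if (tb$inheritance[match(m, tb$name)] == "mtDNA") 1L else 2L
      nids <- vapply(samples[[m]], function(s) length(.parseHapIds(s)), integer(1))
      bad <- which(nids != want & nzchar(trimws(samples[[m]])))
      if (length(bad))
        stop("input error: individual '", samples$individual_id[bad[1L]],
             "' has ", nids[bad[1L]], " haplotype ids at ",
             tb$inheritance[match(m, tb$name)], " marker '", m,
             "' (expected ", want, ")")
    }
  }
  samples
}

#' Write the sample metadata table
#'
#' @param samples sample metadata data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a MarkerRegistry
#'
#' @param table data.frame with columns `name`, `chromosome`, `inheritance`,
#'   `length`, `functional_class`.
#' @param coding named list of coding-interval data.frames (`start`, `end`,
#'   `frame`, `strand`), 1-based closed coordinates; markers absent from the
#'   list get no coding intervals.
#' @return a [MarkerRegistry-class].
#' @export
MarkerRegistry <- function(table, coding = list()) {
  empty <- data.frame(start = integer(), end = integer(),
                      frame = integer(), strand = character())
  full <- setNames(rep(list(empty), nrow(table)), table$name)
  for (nm in intersect(names(coding), table$name)) full[[nm]] <- coding[[nm]]
  table$length <- as.integer(table$length)
  methods::new("MarkerRegistry", table = table, coding = full)
}

.formatIntervals <- function(iv) {
  if (nrow(iv) == 0L) return("")
  paste(sprintf("%d-%d:%d:%s", iv$start, iv$end, iv$frame, iv$strand),
        collapse = ", ")
}

.parseIntervals <- function(s, marker) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s))
    return(data.frame(start = integer(), end = integer(),
                      frame = integer(), strand = character()))
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  m <- regmatches(parts, regexec("^(\\d+)-(\\d+):([123]):([+-])$", parts))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("config error: marker '", marker, "': cannot parse coding interval '",
         parts[bad][1L], "' (expected start-end:frame:strand)")
  data.frame(start = as.integer(vapply(m, `[`, "", 2L)),
             end = as.integer(vapply(m, `[`, "", 3L)),
             frame = as.integer(vapply(m, `[`, "", 4L)),
             strand = vapply(m, `[`, "", 5L))
}

#' Read the marker registry from a DCF config file
#'
#' The registry is a flat key-value file with one record per marker (records
#' separated by blank lines), fields `name`, `chromosome`, `inheritance`,
#' `length`, `functional_class` and optionally `coding`, the latter a
#' comma-separated list of `start-end:frame:strand` intervals in 1-based
#' closed coordinates on the alignment.
#'
#' @param path config file.
#' @return a [MarkerRegistry-class].  Overlapping coding intervals raise a
#'   config error.
#' @export
readMarkerRegistry <- function(path) {
  if (!file.exists(path)) stop("input error: no such file: ", path)
  dcf <- read.dcf(path)
  if (nrow(dcf) == 0L)
    return(MarkerRegistry(data.frame(name = character(), chromosome = character(),
                                     inheritance = character(), length = integer(),
                                     functional_class = character())))
  dcf <- as.data.frame(dcf, stringsAsFactors = FALSE)
  need <- c("name", "inheritance", "length")
  if (!all(need %in% names(dcf)) || anyNA(dcf[need]))
    stop("config error: every registry record needs name, inheritance and length")
  if (!"chromosome" %in% names(dcf)) dcf$chromosome <- NA_character_
  if (!"functional_class" %in% names(dcf)) dcf$functional_class <- "intergenic"
  tb <- data.frame(name = dcf$name, chromosome = dcf$chromosome,
                   inheritance = dcf$inheritance,
                   length = as.integer(dcf$length),
                   functional_class = dcf$functional_class)
  coding <- list()
  if ("coding" %in% names(dcf))
    coding <- setNames(lapply(seq_len(nrow(dcf)), function(i)
      .parseIntervals(dcf$coding[i], dcf$name[i])), dcf$name)
  out <- MarkerRegistry(tb, coding)
  methods::validObject(out)
  out
}

#' Write a marker registry to a DCF config file
#'
#' @param x a [MarkerRegistry-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMarkerRegistry <- function(x, path) {
  tb <- registryTable(x)
  m <- cbind(as.matrix(tb),
             coding = vapply(tb$name, function(nm)
               .formatIntervals(x@coding[[nm]]), ""))
  write.dcf(m, path)
  invisible(path)
}

#' Subset an alignment to the haplotypes of one cohort
#'
#' Retains, in alignment order, exactly the sequences whose ids are listed in
#' the metadata rows of the requested cohort for this marker.  The resulting
#' N equals the summed per-individual haplotype counts of the cohort.
#'
#' @param alignment a [LocusAlignment-class].
#' @param samples sample metadata data.frame (see [readSampleTable()]).
#' @param cohort `"wild"` or `"domestic"`.
#' @return a [LocusAlignment-class] holding the cohort's sequences.
#' @export
cohortSlice <- function(alignment, samples, cohort) {
  cohort <- match.arg(cohort, COHORT_LEVELS)
  m <- marker(alignment)
  if (!m %in% names(samples))
    stop("validation error: sample table has no column for marker '", m, "'")
  ids <- unlist(lapply(samples[[m]][samples$cohort == cohort], .parseHapIds),
                use.names = FALSE)
  if (anyDuplicated(ids))
    stop("validation error: haplotype id claimed by more than one use in cohort '",
         cohort, "' at marker '", m, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(ids, names(sequences(alignment)))
  if (length(missing))
    stop("validation error: metadata references absent sequence(s) at marker '",
         m, "': ", paste(head(missing, 3L), collapse = ", "))
  keep <- names(sequences(alignment)) %in% ids
  methods::new("LocusAlignment", marker = m, seqs = sequences(alignment)[keep])
}

#' Construct and validate a MultiLocusDataset
#'
#' @param alignments named list of [LocusAlignment-class] objects (names must
#'   equal the markers' own names).
#' @param samples sample metadata data.frame.
#' @param registry a [MarkerRegistry-class].
#' @param check run [validateDataset()] (default TRUE).
#' @return a [MultiLocusDataset-class].
#' @export
MultiLocusDataset <- function(alignments, samples, registry, check = TRUE) {
  names(alignments) <- vapply(alignments, marker, "")
  x <- methods::new("MultiLocusDataset", alignments = alignments,
                    samples = samples, registry = registry)
  if (check) validateDataset(x)
  x
}

#' Cross-validate alignments, metadata and registry
#'
#' Checks that, for every marker, the set of sequence ids present in the
#' alignment equals the set referenced by the metadata (each exactly once),
#' that haplotype-id counts match the marker's inheritance mode, and that all
#' alignment lengths match the registry.
#'
#' @param x a [MultiLocusDataset-class].
#' @return `x`, invisibly; errors describe the first inconsistency found.
#' @export
validateDataset <- function(x) {
  tb <- registryTable(registry(x))
  validateSampleTable(samples(x), registry(x))
  for (m in names(alignments(x))) {
    aln <- alignments(x)[[m]]
    if (!m %in% tb$name)
      stop("validation error: marker '", m, "' missing from registry")
    if (alignmentLength(aln) != tb$length[match(m, tb$name)])
      stop("validation error: marker '", m, "' alignment length ",
           alignmentLength(aln), " != registry length ",
           tb$length[match(m, tb$name)])
    if (!m %in% names(samples(x)))
      stop("validation error: sample table has no column for marker '", m, "'")
    ids <- unlist(lapply(samples(x)[[m]], .parseHapIds), use.names = FALSE)
    if (anyDuplicated(ids))
      stop("validation error: haplotype id referenced twice at marker '", m,
           "': ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
    have <- names(sequences(aln))
    if (!setequal(ids, have)) {
      orphan <- setdiff(have, ids)
      if (length(orphan))
        stop("validation error: sequence(s) with no metadata owner at marker '",
             m, "': ", paste(head(orphan, 3L), collapse = ", "))
      stop("validation error: metadata references absent sequence(s) at marker '",
           m, "': ", paste(head(setdiff(ids, have), 3L), collapse = ", "))
    }
  }
  invisible(x)
}

#' Read / write a dataset directory
#'
#' A dataset directory holds `alignments/<marker>.fasta` (one FASTA per
#' marker), `samples.tsv` and `markers.dcf`.
#'
#' @param dir dataset directory.
#' @param check validate after reading (default TRUE).
#' @return `readDataset` returns a [MultiLocusDataset-class]; `writeDataset`
#'   returns `dir` invisibly.
#' @export
readDataset <- function(dir, check = TRUE) {
  reg <- readMarkerRegistry(file.path(dir, "markers.dcf"))
  smp <- readSampleTable(file.path(dir, "samples.tsv"), reg)
  alns <- lapply(registryTable(reg)$name, function(m)
    readLocusAlignment(file.path(dir, "alignments", paste0(m, ".fasta")), m))
  MultiLocusDataset(alns, smp, reg, check = check)
}

#' @rdname readDataset
#' @param x a [MultiLocusDataset-class].
#' @export
writeDataset <- function(x, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  writeMarkerRegistry(registry(x), file.path(dir, "markers.dcf"))
  writeSampleTable(samples(x), file.path(dir, "samples.tsv"))
  for (m in names(alignments(x)))
    writeLocusAlignment(alignments(x)[[m]],
                        file.path(dir, "alignments", paste0(m, ".fasta")))
  invisible(dir)
}
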