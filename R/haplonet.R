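# Median-joining haplotype network construction.

.hammingMatrix <- function(haps) {
  n <- length(haps)
  if (n == 1L) return(matrix(0L, 1L, 1L, dimnames = list(haps, haps)))
  m <- do.call(rbind, strsplit(haps, ""))
  d <- .pairwiseDiffMatrix(m)
  dimnames(d) <- list(haps, haps)
  d
}

# total weight of the minimum spanning tree on a distance matrix
.mstCost <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g, algorithm = "prim"))$weight)
}

# epsilon-relaxed minimum spanning network: edge (u, v) is included when its
# weight does not exceed the level at which u and v first become connected
# (the minimax path weight) plus epsilon
.msnEdges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n <= 1L)
    return(data.frame(from = integer(), to = integer(), weight = numeric()))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  # connection level per pair via level-by-level union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  connLevel <- matrix(Inf, n, n)
  for (lev in sort(unique(w))) {
    at <- which(w == lev)
    for (e in at) {
      a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
      if (a != b) parent[a] <- b
    }
    # record newly connected pairs
    roots <- vapply(seq_len(n), find, integer(1))
    newly <- outer(roots, roots, "==") & !is.finite(connLevel)
    connLevel[newly] <- lev
  }
  keep <- vapply(seq_along(w), function(e) {
    w[e] <= connLevel[pairs[e, 1L], pairs[e, 2L]] + epsilon
  }, logical(1))
  data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L], weight = w[keep])
}

# majority consensus of three equal-length haplotype strings; all-distinct
# positions resolve to the lexicographically smallest character
.medianVector <- function(h1, h2, h3) {
  m <- rbind(strsplit(h1, "")[[1L]], strsplit(h2, "")[[1L]],
             strsplit(h3, "")[[1L]])
  paste(apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    if (tb[1L] >= 2L) names(tb)[1L] else min(col)
  }), collapse = "")
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network of a set of observed haplotypes: starting
#' from the epsilon-relaxed minimum spanning network under Hamming distance,
#' median (Steiner) vectors -- majority consensus sequences of triplets of
#' mutually linked nodes -- are added greedily whenever they reduce the total
#' cost (minimum-spanning-tree weight) of the node set; the iteration stops
#' when no candidate median reduces the cost, and medians whose removal leaves
#' the cost unchanged are pruned.  All ties (equal-cost links and medians) are
#' broken lexicographically by haplotype string, making the construction
#' deterministic.
#'
#' Columns containing `-` or `N` are excluded before distances are computed,
#' consistent with the package-wide complete-deletion policy.
#'
#' @param x a [LocusAlignment-class], or a character vector of equal-length
#'   haplotype strings (optionally named) with `counts` giving frequencies.
#' @param counts integer frequencies per haplotype (ignored when `x` is an
#'   alignment, where frequencies come from [haplotypeTable()]).
#' @param epsilon nonnegative integer relaxation of the minimum spanning
#'   network (default 0, the usual choice).
#' @param composition optional matrix (haplotype string x category) of counts,
#'   e.g. per-region composition, copied onto the observed nodes.
#' @return a [HaploNetwork-class].
#' @export
medianJoining <- function(x, counts = NULL, epsilon = 0L, composition = NULL) {
  if (is(x, "LocusAlignment")) {
    tab <- haplotypeTable(x)
    haps <- names(tab); counts <- unname(tab)
  } else {
    haps <- as.character(x)
    if (is.null(counts)) counts <- rep(1L, length(haps))
    if (length(unique(nchar(haps))) > 1L)
      stop("haplotypes must have equal length")
  }
  if (length(haps) == 0L)
    return(methods::new("HaploNetwork",
                        nodes = data.frame(id = character(),
                                           haplotype = character(),
                                           frequency = integer(),
                                           median = logical()),
                        edges = data.frame(from = character(), to = character(),
                                           weight = numeric()),
                        connected = FALSE))
  observed <- haps
  nodes <- sort(unique(haps))
  repeat {
    d <- .hammingMatrix(nodes)
    base <- .mstCost(d)
    edges <- .msnEdges(d, epsilon)
    adj <- matrix(FALSE, length(nodes), length(nodes))
    adj[cbind(edges$from, edges$to)] <- TRUE
    adj <- adj | t(adj)
    # candidate medians from mutually linked triplets
    cand <- character()
    if (length(nodes) >= 3L) {
      trip <- combn(length(nodes), 3L)
      for (t in seq_len(ncol(trip))) {
        i <- trip[1L, t]; j <- trip[2L, t]; k <- trip[3L, t]
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2L) next  # not a linked triplet
        mv <- .medianVector(nodes[i], nodes[j], nodes[k])
        if (!mv %in% nodes) cand <- c(cand, mv)
      }
    }
    cand <- sort(unique(cand))
    if (!length(cand)) break
    gain <- vapply(cand, function(mv)
      base - .mstCost(.hammingMatrix(c(nodes, mv))), numeric(1))
    best <- which(gain > 0)
    if (!length(best)) break
    # lexicographically first among maximal-gain candidates
    pick <- cand[best][order(-gain[best], cand[best])][1L]
    nodes <- sort(c(nodes, pick))
  }
  # prune medians that no longer pay for themselves
  repeat {
    medians <- setdiff(nodes, observed)
    if (!length(medians)) break
    cost <- .mstCost(.hammingMatrix(nodes))
    removable <- vapply(medians, function(mv)
      .mstCost(.hammingMatrix(setdiff(nodes, mv))) <= cost, logical(1))
    if (!any(removable)) break
    nodes <- setdiff(nodes, sort(medians[removable])[1L])
  }
  d <- .hammingMatrix(nodes)
  edges <- .msnEdges(d, epsilon)
  isMedian <- !(nodes %in% observed)
  freq <- integer(length(nodes))
  obsTab <- tapply(counts, haps, sum)
  freq[!isMedian] <- as.integer(obsTab[nodes[!isMedian]])
  ids <- ifelse(isMedian, paste0("mv", cumsum(isMedian)),
                paste0("H", cumsum(!isMedian)))
  nodeDf <- data.frame(id = ids, haplotype = nodes, frequency = freq,
                       median = isMedian)
  if (!is.null(composition)) {
    comp <- matrix(0L, length(nodes), ncol(composition),
                   dimnames = list(NULL, colnames(composition)))
    hit <- match(nodes, rownames(composition))
    comp[!is.na(hit), ] <- composition[hit[!is.na(hit)], , drop = FALSE]
    nodeDf <- cbind(nodeDf, as.data.frame(comp))
  }
  edgeDf <- data.frame(from = ids[edges$from], to = ids[edges$to],
                       weight = edges$weight)
  g <- igraph::graph_from_data_frame(edgeDf, directed = FALSE,
                                     vertices = data.frame(name = ids))
  connected <- igraph::components(g)$no == 1L
  methods::new("HaploNetwork", nodes = nodeDf, edges = edgeDf,
               connected = connected || length(nodes) == 1L)
}

#' Write a haplotype network as plain-text edge and node files
#'
#' @param net a [HaploNetwork-class].
#' @param edgePath,nodePath output TSV paths.
#' @return invisibly, a list of the two paths.
#' @export
writeHaploNetwork <- function(net, edgePath, nodePath) {
  write.table(net@edges, edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net@nodes, nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(edges = edgePath, nodes = nodePath))
}
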