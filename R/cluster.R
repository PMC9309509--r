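## ORF-proximity clustering of scored nodes, span-normalized cluster scoring,
## chimeric-cluster decoupling, and the final PBC filter.

.checkNodes <- function(nodes) {
  need <- c("protein_id", "orf_index", "contig", "score")
  miss <- setdiff(need, names(nodes))
  if (length(miss))
    stop("node table is missing column(s): ", paste(miss, collapse = ", "))
  dup <- nodes$orf_index[duplicated(nodes$orf_index)]
  if (length(dup)) {
    who <- nodes$protein_id[nodes$orf_index %in% dup]
    stop("duplicate orf_index among nodes: ", paste(who, collapse = ", "))
  }
  invisible(nodes)
}

#' Connected components of the ORF-proximity graph
#'
#' Scored nodes (score != 0) are vertices; an edge joins two nodes on the
#' same contig whose ORF indices differ by at most \code{maxGap}. Clusters
#' are the maximal connected components. On a linear genome this equals the
#' maximal runs of genome-sorted same-contig nodes whose consecutive gaps are
#' all <= \code{maxGap}, which is how it is computed. Components mixing
#' up- and down-regulated nodes are kept whole here; chimera handling is a
#' downstream step ([decoupleChimeric()]).
#'
#' @param nodes A data.frame/DataFrame with columns \code{protein_id},
#'   \code{orf_index}, \code{contig}, \code{score}; rows with score 0 are
#'   ignored.
#' @param maxGap Maximum ORF-index difference bridged by an edge (default 5).
#' @return A list of data.frames, one per component, members sorted by
#'   \code{orf_index}; components ordered by (contig appearance, orf_begin).
#' @examples
#' nodes <- data.frame(protein_id = paste0("p", 1:4),
#'                     orf_index = c(10, 12, 15, 22),
#'                     contig = "c1", score = c(10, 5, 10, 5))
#' length(buildComponents(nodes))  # 2: {10,12,15} and {22}
#' @export
buildComponents <- function(nodes, maxGap = 5) {
  stopifnot(maxGap >= 1)
  nodes <- as.data.frame(nodes)
  nodes <- nodes[nodes$score != 0, , drop = FALSE]
  .checkNodes(nodes)
  if (nrow(nodes) == 0L) return(list())
  contigOrder <- unique(nodes$contig)
  nodes <- nodes[order(match(nodes$contig, contigOrder), nodes$orf_index), ,
                 drop = FALSE]
  newContig <- c(TRUE, nodes$contig[-1] != nodes$contig[-nrow(nodes)])
  gap <- c(0, diff(nodes$orf_index))
  breaks <- newContig | gap > maxGap
  comp <- cumsum(breaks)
  unname(split(nodes, comp))
}

#' Span-normalized cluster score
#'
#' The cluster score is the magnitude of the summed member node scores
#' divided by the ORF span (difference between the largest and smallest
#' member ORF numbers), rewarding consistent co-regulation of tightly packed
#' members. Single-node clusters (span 0) use span 1. The alternative
#' \code{mode = "node-mean"} scores a cluster as the magnitude of the mean
#' member score instead.
#'
#' @param scores Member node scores.
#' @param orfIndices Member ORF indices.
#' @param mode \code{"span"} (default) or \code{"node-mean"}.
#' @return Non-negative cluster score.
#' @examples
#' scoreCluster(c(10, 10, 5), c(100, 102, 104))  # 25/4 = 6.25
#' scoreCluster(c(10, -10), c(50, 51))           # 0
#' @export
scoreCluster <- function(scores, orfIndices, mode = c("span", "node-mean")) {
  mode <- match.arg(mode)
  stopifnot(length(scores) == length(orfIndices), length(scores) >= 1L)
  if (mode == "node-mean") return(abs(mean(scores)))
  span <- max(orfIndices) - min(orfIndices)
  abs(sum(scores)) / max(span, 1)
}

## Exact contiguous-partition search (dynamic program).
##
## Members are in ORF order; a partition is a set of cut positions between
## consecutive members. A partition is valid when EVERY part scores >= high
## (the sub-clusters all clear the PBC threshold). Among valid partitions
## the selection is lexicographic:
##   1. fewest parts (the most conservative separation)
##   2. largest total sum of |part score sums|
##   3. leftmost cut positions
## f[i] = best valid partition of members 1..i (NULL when none exists).
## O(n^2) states x O(n) compare.
.bestPartition <- function(scores, orfs, high, mode = "span") {
  n <- length(scores)
  cs <- cumsum(scores)
  partSum <- function(i, j) cs[j] - if (i > 1) cs[i - 1] else 0
  partScore <- function(i, j) {
    if (mode == "node-mean") return(abs(partSum(i, j)) / (j - i + 1))
    abs(partSum(i, j)) / max(orfs[j] - orfs[i], 1)
  }
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$nparts != b$nparts) return(a$nparts < b$nparts)
    if (abs(a$totabs - b$totabs) > 1e-9) return(a$totabs > b$totabs)
    # equal part counts -> equal-length cut vectors; leftmost wins
    d <- which(a$cuts != b$cuts)
    if (length(d)) return(a$cuts[d[1]] < b$cuts[d[1]])
    FALSE
  }
  f <- vector("list", n + 1L)
  f[[1L]] <- list(nparts = 0L, totabs = 0, cuts = integer())
  for (i in seq_len(n)) {
    best <- NULL
    for (j in 0:(i - 1L)) {
      prev <- f[[j + 1L]]
      if (is.null(prev) || partScore(j + 1L, i) < high) next
      cand <- list(
        nparts = prev$nparts + 1L,
        totabs = prev$totabs + abs(partSum(j + 1L, i)),
        cuts = if (j > 0L) c(prev$cuts, j) else prev$cuts)
      if (better(cand, best)) best <- cand
    }
    f[[i + 1L]] <- best
  }
  f[[n + 1L]]
}

#' Decouple a chimeric cluster
#'
#' A connected cluster whose score falls in the intermediate band
#' [\code{low}, \code{high}) may be a chimera: two or more genuine clusters
#' diluted by weak or opposing nodes between them. This searches all
#' contiguous partitions (split points between consecutive members in ORF
#' order) for one of at least two parts in which every sub-cluster scores
#' >= \code{high}. When one exists, the partition with the fewest parts
#' (ties: largest total |part score sum|, then leftmost split positions) is
#' returned and every part is labelled with a letter suffix a, b, c ... in
#' ORF order. Otherwise, and for clusters outside the band, the cluster is
#' returned unchanged. The search is an exact O(n^2) dynamic program over
#' split positions, equivalent to enumerating all 2^(n-1) contiguous
#' partitions.
#'
#' @param members Data.frame of member nodes (columns \code{protein_id},
#'   \code{orf_index}, \code{contig}, \code{score}), sorted by ORF index.
#' @param low,high Score band checked for chimeras (defaults 1.5 and 3.0);
#'   \code{high} is also the sub-cluster acceptance threshold.
#' @param mode Cluster score mode, see [scoreCluster()].
#' @return A list of member data.frames: length 1 (unchanged) or one entry
#'   per part, each with a \code{part_letter} attribute.
#' @export
decoupleChimeric <- function(members, low = 1.5, high = 3.0,
                             mode = c("span", "node-mean")) {
  mode <- match.arg(mode)
  members <- as.data.frame(members)
  members <- members[order(members$orf_index), , drop = FALSE]
  whole <- scoreCluster(members$score, members$orf_index, mode)
  if (whole < low || whole >= high) return(list(members))
  best <- .bestPartition(members$score, members$orf_index, high, mode)
  if (is.null(best) || best$nparts < 2L) return(list(members))
  bounds <- c(0L, best$cuts, nrow(members))
  parts <- lapply(seq_len(length(bounds) - 1L), function(k) {
    part <- members[(bounds[k] + 1L):bounds[k + 1L], , drop = FALSE]
    attr(part, "part_letter") <- letters[k]
    part
  })
  parts
}

#' Filter clusters into annotated PBCs
#'
#' Keeps clusters with \code{cluster_score >= minScore} and
#' \code{n_nodes >= minNodes} as the annotated PBC set; clusters scoring in
#' [\code{low}, \code{minScore}) are retained as a secondary candidate list
#' for reporting. Operates on the cluster table of a [PBCSet-class].
#'
#' @param pbcs Cluster DataFrame/data.frame with columns
#'   \code{cluster_score} and \code{n_nodes}.
#' @param minScore Annotation score threshold (default 3.0, inclusive).
#' @param minNodes Minimum member count (default 5).
#' @param low Lower bound of the candidate band (default 1.5).
#' @return \code{pbcs} with logical columns \code{annotated} and
#'   \code{candidate} added, sorted by (contig appearance, orf_begin).
#' @export
filterPBCs <- function(pbcs, minScore = 3.0, minNodes = 5, low = 1.5) {
  pbcs$annotated <- pbcs$cluster_score >= minScore & pbcs$n_nodes >= minNodes
  pbcs$candidate <- pbcs$cluster_score >= low & pbcs$cluster_score < minScore
  ord <- order(match(pbcs$contig, unique(pbcs$contig)), pbcs$orf_begin)
  pbcs[ord, , drop = FALSE]
}

## Build one cluster-table row from a member data.frame.
.clusterRow <- function(members, id, decoupledFrom = NA_character_) {
  sumScore <- sum(members$score)
  S4Vectors::DataFrame(
    cluster_id = id,
    contig = members$contig[1],
    orf_begin = min(members$orf_index),
    orf_end = max(members$orf_index),
    span = max(members$orf_index) - min(members$orf_index),
    n_nodes = nrow(members),
    sum_score = sumScore,
    cluster_score = NA_real_,
    direction = as.integer(sign(sumScore)),
    decoupled_from = decoupledFrom,
    members = IRanges::CharacterList(list(members$protein_id)))
}

#' Identify proteomining-based clusters
#'
#' Runs the clustering stage end to end on a scored experiment: builds the
#' ORF-proximity components over nodes with score != 0, scores each
#' component, decouples chimeric components scoring in
#' [\code{scoreLow}, \code{scoreHigh}), and flags the final annotated PBCs
#' (score >= \code{scoreHigh} and >= \code{minNodes} members) and the
#' candidate band. Cluster IDs number every component in genome order;
#' decoupled sub-clusters carry their parent's number plus a letter.
#'
#' @param x A [ProteomineExperiment-class] after [scoreNodes()].
#' @param maxGap Maximum ORF gap bridged by an edge (default 5).
#' @param scoreLow,scoreHigh Chimera band and annotation threshold
#'   (defaults 1.5 and 3.0).
#' @param minNodes Minimum members for annotation (default 5).
#' @param scoreMode \code{"span"} (default) or \code{"node-mean"}, see
#'   [scoreCluster()].
#' @param ... Unused.
#' @return A [PBCSet-class].
#' @export
#' @rdname findPBCs
setMethod("findPBCs", "ProteomineExperiment",
          function(x, maxGap = 5, scoreLow = 1.5, scoreHigh = 3.0,
                   minNodes = 5, scoreMode = c("span", "node-mean"), ...) {
  scoreMode <- match.arg(scoreMode)
  stopifnot(scoreLow > 0, scoreLow < scoreHigh)
  nodes <- as.data.frame(nodeTable(x, scoredOnly = TRUE))
  if ("start" %in% names(SummarizedExperiment::rowData(x))) {
    rd <- SummarizedExperiment::rowData(x)
    nodes$start <- rd$start[match(nodes$protein_id, rownames(x))]
    nodes$end <- rd$end[match(nodes$protein_id, rownames(x))]
  }
  comps <- buildComponents(nodes, maxGap = maxGap)
  compScore <- vapply(comps, function(m)
    scoreCluster(m$score, m$orf_index, scoreMode), numeric(1))

  nGeLowPre <- sum(compScore >= scoreLow)
  nGeHighPre <- sum(compScore >= scoreHigh)

  rows <- list()
  nodeCluster <- character(nrow(nodes))
  names(nodeCluster) <- nodes$protein_id
  nDecoupled <- 0L
  for (k in seq_along(comps)) {
    id <- as.character(k)
    parts <- decoupleChimeric(comps[[k]], low = scoreLow, high = scoreHigh,
                              mode = scoreMode)
    if (length(parts) > 1L) {
      nDecoupled <- nDecoupled + 1L
      for (part in parts) {
        pid <- paste0(id, attr(part, "part_letter"))
        rows[[pid]] <- .clusterRow(part, pid, decoupledFrom = id)
        nodeCluster[part$protein_id] <- pid
      }
    } else {
      rows[[id]] <- .clusterRow(parts[[1L]], id)
      nodeCluster[parts[[1L]]$protein_id] <- id
    }
  }
  pbcs <- if (length(rows)) do.call(rbind, unname(rows)) else
    S4Vectors::DataFrame(
      cluster_id = character(), contig = character(),
      orf_begin = integer(), orf_end = integer(), span = integer(),
      n_nodes = integer(), sum_score = integer(),
      cluster_score = numeric(), direction = integer(),
      decoupled_from = character(),
      members = IRanges::CharacterList())
  if (nrow(pbcs)) {
    pbcs$cluster_score <- vapply(seq_len(nrow(pbcs)), function(i) {
      m <- match(pbcs$members[[i]], nodes$protein_id)
      scoreCluster(nodes$score[m], nodes$orf_index[m], scoreMode)
    }, numeric(1))
  }
  pbcs$annotated <- pbcs$cluster_score >= scoreHigh & pbcs$n_nodes >= minNodes
  pbcs$candidate <- pbcs$cluster_score >= scoreLow & pbcs$cluster_score < scoreHigh
  ## report clusters in the candidate band and above; sub-threshold noise
  ## components are only counted in the summary, but decoupled parts are kept
  ## for bookkeeping
  keep <- pbcs$cluster_score >= scoreLow | !is.na(pbcs$decoupled_from)
  pbcs <- pbcs[keep, , drop = FALSE]
  ord <- order(match(pbcs$contig, unique(nodes$contig)), pbcs$orf_begin)
  pbcs <- pbcs[ord, , drop = FALSE]
  rownames(pbcs) <- NULL

  nodesDF <- S4Vectors::DataFrame(nodes)
  nodesDF$cluster_id <- nodeCluster[nodes$protein_id]

  summary <- list(
    n_scored_nodes = nrow(nodes),
    n_components = length(comps),
    n_ge_low = nGeLowPre,
    n_ge_high_pre = nGeHighPre,
    n_decoupled = nDecoupled,
    n_ge_high = sum(pbcs$cluster_score >= scoreHigh),
    n_annotated = sum(pbcs$annotated),
    n_candidate = sum(pbcs$candidate))
  params <- list(max_gap = maxGap, score_low = scoreLow,
                 score_high = scoreHigh, min_nodes = minNodes,
                 score_mode = scoreMode)
  methods::new("PBCSet", nodes = nodesDF, pbcs = pbcs,
               params = params, summary = summary)
})

## ---- PBCSet accessors ----

#' Accessors for PBCSet
#'
#' @param x A [PBCSet-class].
#' @param ... Unused.
#' @return \code{pbcTable}: the full cluster DataFrame (candidate band and
#'   above, plus all decoupled parts). \code{annotatedPBCs}: the annotated
#'   subset (score and member-count thresholds met). \code{candidatePBCs}:
#'   the intermediate band. \code{pbcSummary}: named list of stage counts.
#' @name PBCSet-accessors
NULL

#' @rdname PBCSet-accessors
#' @export
setMethod("pbcTable", "PBCSet", function(x, ...) x@pbcs)

#' @rdname PBCSet-accessors
#' @export
setMethod("annotatedPBCs", "PBCSet", function(x, ...)
  x@pbcs[x@pbcs$annotated, , drop = FALSE])

#' @rdname PBCSet-accessors
#' @export
setMethod("candidatePBCs", "PBCSet", function(x, ...)
  x@pbcs[x@pbcs$candidate, , drop = FALSE])

#' @rdname PBCSet-accessors
#' @export
setMethod("pbcSummary", "PBCSet", function(x) x@summary)

#' @rdname PBCSet-accessors
#' @export
pbcNodes <- function(x) x@nodes

#' @rdname PBCSet-accessors
#' @export
pbcParams <- function(x) x@params

setMethod("show", "PBCSet", function(object) {
  s <- object@summary
  p <- object@params
  cat("class: PBCSet\n")
  cat(sprintf("%d scored nodes in %d connected components (max gap %d ORFs)\n",
              s$n_scored_nodes, s$n_components, p$max_gap))
  cat(sprintf("%d clusters scored >= %.2g; among these %d scored >= %.2g\n",
              s$n_ge_low, p$score_low, s$n_ge_high_pre, p$score_high))
  cat(sprintf("%d chimeric cluster(s) decoupled; %d clusters >= %.2g after decoupling\n",
              s$n_decoupled, s$n_ge_high, p$score_high))
  cat(sprintf("%d annotated PBCs (score >= %.2g, >= %d nodes); %d candidates\n",
              s$n_annotated, p$score_high, p$min_nodes, s$n_candidate))
  invisible(NULL)
})

## ---- interval and graph exports ----

#' Genomic ranges of PBCs
#'
#' Converts clusters to a \link[GenomicRanges]{GRanges} spanning the member
#' ORFs. Genomic coordinates are used when the ORF map carried them;
#' otherwise ORF indices serve as coordinates (useful for plotting, not for
#' export against an assembly).
#'
#' @param x A [PBCSet-class].
#' @param annotatedOnly Restrict to annotated PBCs (default TRUE).
#' @param ... Unused.
#' @return A GRanges with metadata columns cluster_id, n_nodes,
#'   cluster_score and direction.
#' @export
#' @rdname pbcRanges
setMethod("pbcRanges", "PBCSet", function(x, annotatedOnly = TRUE, ...) {
  pbcs <- if (annotatedOnly) annotatedPBCs(x) else pbcTable(x)
  nodes <- as.data.frame(x@nodes)
  haveCoords <- all(c("start", "end") %in% names(nodes)) &&
    !anyNA(nodes$start) && !anyNA(nodes$end)
  if (nrow(pbcs) == 0L)
    return(GenomicRanges::GRanges())
  lims <- t(vapply(seq_len(nrow(pbcs)), function(i) {
    m <- nodes[match(pbcs$members[[i]], nodes$protein_id), , drop = FALSE]
    if (haveCoords) c(min(m$start), max(m$end))
    else c(min(m$orf_index), max(m$orf_index))
  }, numeric(2)))
  gr <- GenomicRanges::GRanges(
    seqnames = pbcs$contig,
    ranges = IRanges::IRanges(start = lims[, 1], end = lims[, 2]),
    cluster_id = pbcs$cluster_id,
    n_nodes = pbcs$n_nodes,
    cluster_score = pbcs$cluster_score,
    direction = pbcs$direction)
  names(gr) <- paste0("PBC_", pbcs$cluster_id)
  gr
})

#' Export PBC intervals
#'
#' Writes annotated PBC ranges as BED (0-based half-open) or GFF3 (1-based
#' inclusive) via \pkg{rtracklayer}. Requires genomic coordinates in the ORF
#' map.
#'
#' @param x A [PBCSet-class].
#' @param path Output file; format inferred from the extension
#'   (\code{.bed}, \code{.gff3}/\code{.gff}).
#' @param annotatedOnly Restrict to annotated PBCs (default TRUE).
#' @return The path, invisibly.
#' @export
exportPBCIntervals <- function(x, path, annotatedOnly = TRUE) {
  gr <- pbcRanges(x, annotatedOnly = annotatedOnly)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    ## BED scores must be 0-1000 integers
    gr$score <- pmin(1000L, as.integer(round(gr$cluster_score * 100)))
    gr$name <- paste0("PBC_", gr$cluster_id)
  }
  rtracklayer::export(gr, path)
  invisible(path)
}

#' Export the node graph as DOT
#'
#' Writes the scored-node proximity graph (nodes with score != 0, edges
#' between same-contig nodes within the ORF gap) in Graphviz DOT format for
#' figure-style visualization.
#'
#' @param x A [PBCSet-class].
#' @param path Output .dot file.
#' @return The path, invisibly.
#' @export
exportGraphDOT <- function(x, path) {
  nodes <- as.data.frame(x@nodes)
  maxGap <- x@params$max_gap
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph pbc {", con)
  for (i in seq_len(nrow(nodes)))
    writeLines(sprintf('  "%s" [label="%s\\n%+d" color=%s];',
                       nodes$protein_id[i], nodes$protein_id[i],
                       nodes$score[i],
                       if (nodes$score[i] > 0) "red" else "blue"), con)
  ord <- order(match(nodes$contig, unique(nodes$contig)), nodes$orf_index)
  nodes <- nodes[ord, ]
  for (i in seq_len(nrow(nodes))) {
    j <- i + 1L
    while (j <= nrow(nodes) && nodes$contig[j] == nodes$contig[i] &&
           nodes$orf_index[j] - nodes$orf_index[i] <= maxGap) {
      writeLines(sprintf('  "%s" -- "%s";', nodes$protein_id[i],
                         nodes$protein_id[j]), con)
      j <- j + 1L
    }
  }
  writeLines("}", con)
  invisible(path)
}
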