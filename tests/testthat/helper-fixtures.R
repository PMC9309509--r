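# Fixture builders and independent oracles shared across tests.

# Small ProteomineExperiment built in code. `counts` is a proteins x samples
# matrix; defaults give every protein an equal length so NSAF is proportional
# to counts within a sample.
makePE <- function(counts, lengths = rep(100L, nrow(counts)),
                   groups = NULL, producing = "producing",
                   orf = seq_len(nrow(counts)),
                   contig = rep("c1", nrow(counts))) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("P", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(groups)) {
    half <- ncol(counts) %/% 2
    groups <- setNames(rep(c("growth", "producing"),
                           c(half, ncol(counts) - half)), colnames(counts))
  }
  orfMap <- data.frame(protein_id = rownames(counts), orf_index = orf,
                       contig = contig, stringsAsFactors = FALSE)
  ProteomineExperiment(counts, lengths = lengths, groups = groups,
                       producing = producing, orfMap = orfMap)
}

# A PE with the NSAF assay set to exact hand-chosen abundances, bypassing the
# count-derived computation, to test the differential-scoring math alone.
makeScoredInput <- function(nsafMatrix, orf = seq_len(nrow(nsafMatrix)),
                            contig = rep("c1", nrow(nsafMatrix))) {
  counts <- matrix(1L, nrow(nsafMatrix), ncol(nsafMatrix),
                   dimnames = dimnames(nsafMatrix))
  pe <- makePE(counts, orf = orf, contig = contig)
  SummarizedExperiment::assay(pe, "nsaf") <- nsafMatrix
  pe
}

# Brute-force connected components of the ORF-proximity graph via igraph:
# an edge joins nodes on the same contig with |delta orf| <= maxGap.
# Returns a list of member index sets (into `nodes`), each sorted by
# orf_index, ordered by (contig appearance, smallest orf).
oracleComponents <- function(nodes, maxGap = 5) {
  nodes <- as.data.frame(nodes)
  nodes <- nodes[nodes$score != 0, , drop = FALSE]
  n <- nrow(nodes)
  if (n == 0) return(list())
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    nodes$contig[i] == nodes$contig[j] &
      abs(nodes$orf_index[i] - nodes$orf_index[j]) <= maxGap)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(n), memb)
  comps <- lapply(comps, function(ix) ix[order(nodes$orf_index[ix])])
  firstOrf <- vapply(comps, function(ix) min(nodes$orf_index[ix]), numeric(1))
  contigRank <- vapply(comps, function(ix)
    match(nodes$contig[ix[1]], unique(nodes$contig)), numeric(1))
  comps[order(contigRank, firstOrf)]
}

# Exhaustive contiguous-partition search: enumerates all 2^(n-1) split masks.
# A partition is valid when it has >= 2 parts and EVERY part scores >= high;
# among valid partitions the one with fewest parts wins (ties: largest total
# |part sum|, then leftmost cuts). Returns the list of part index ranges, or
# NULL when no valid partition exists.
oraclePartition <- function(scores, orfs, high = 3) {
  n <- length(scores)
  stopifnot(n <= 16)
  partScore <- function(i, j)
    abs(sum(scores[i:j])) / max(orfs[j] - orfs[i], 1)
  betterThan <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$nparts != b$nparts) return(a$nparts < b$nparts)
    if (abs(a$totabs - b$totabs) > 1e-9) return(a$totabs > b$totabs)
    d <- which(a$cuts != b$cuts)
    if (length(d)) return(a$cuts[d[1]] < b$cuts[d[1]])
    FALSE
  }
  best <- NULL
  bestKey <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {   # mask 0 = no cuts, never valid
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    totabs <- 0
    ok <- TRUE
    parts <- vector("list", length(bounds) - 1)
    for (k in seq_len(length(bounds) - 1)) {
      i <- bounds[k] + 1; j <- bounds[k + 1]
      parts[[k]] <- i:j
      if (partScore(i, j) < high) { ok <- FALSE; break }
      totabs <- totabs + abs(sum(scores[i:j]))
    }
    if (!ok) next
    key <- list(nparts = length(parts), totabs = totabs, cuts = cuts)
    if (betterThan(key, bestKey)) {
      bestKey <- key
      best <- parts
    }
  }
  best
}

# Random node configuration on a small genome, for oracle-equivalence checks.
randomNodes <- function(nNodes, nOrfs = 60, nContigs = 2) {
  orf <- sort(sample(nOrfs, nNodes))
  data.frame(protein_id = paste0("p", seq_len(nNodes)),
             orf_index = orf,
             contig = paste0("ctg", 1 + (orf - 1) %/% ceiling(nOrfs / nContigs)),
             score = sample(c(-10L, -5L, 5L, 10L), nNodes, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Write a well-formed count table TSV; returns the path.
writeCountTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
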