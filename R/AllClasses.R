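#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats setNames
NULL

#' ProteomineExperiment: spectral counts over an ordered ORF list
#'
#' An S4 container for a two-group label-free proteomics comparison, extending
#' \linkS4class{SummarizedExperiment}. The \code{"counts"} assay holds integer
#' spectral counts (proteins x samples). Row metadata carries the protein
#' length in amino acids (\code{length}), the consecutive ORF index along the
#' assembly (\code{orf_index}), the contig (\code{contig}) and, optionally,
#' 1-based genomic \code{start}/\code{end}/\code{strand}. Column metadata
#' carries the sample \code{group}; \code{metadata(x)$producing} names the
#' group representing the secondary-metabolite-producing (nutrient-starved)
#' state, the other group being the growth-phase background.
#'
#' Downstream steps add assays and row columns in place: [computeNSAF()] adds
#' the \code{"nsaf"} assay, [imputeAbundance()] applies the detection filter
#' and floor imputation, and [scoreNodes()] adds the differential-expression
#' columns and node scores.
#'
#' @slot producing Character scalar, the producing-group label (also mirrored
#'   in \code{metadata()} for provenance).
#' @export
setClass("ProteomineExperiment",
  contains = "SummarizedExperiment",
  representation(producing = "character"))

setValidity("ProteomineExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("length", "orf_index", "contig"))
    if (!col %in% names(rd)) msg <- c(msg, sprintf("rowData column '%s' is required", col))
  if ("length" %in% names(rd) && any(rd$length <= 0))
    msg <- c(msg, "all protein lengths must be > 0")
  if ("orf_index" %in% names(rd) && anyDuplicated(rd$orf_index))
    msg <- c(msg, "orf_index values must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate protein IDs")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% names(cd)) msg <- c(msg, "colData column 'group' is required")
  else {
    grps <- unique(as.character(cd$group))
    if (length(grps) != 2L)
      msg <- c(msg, sprintf("exactly two sample groups are required (found %d)", length(grps)))
    if (length(object@producing) != 1L || !object@producing %in% grps)
      msg <- c(msg, "'producing' must name one of the two groups")
  }
  if (length(msg)) msg else TRUE
})

#' PBCSet: proteomining-based clusters from one comparison
#'
#' Result container returned by [findPBCs()]. Holds the scored node table,
#' the cluster table after chimeric decoupling, and the thresholds used.
#'
#' @slot nodes A \link[S4Vectors]{DataFrame} of clustered nodes (score != 0):
#'   protein_id, orf_index, contig, means, fold_change, p_value, score and
#'   the id of the cluster each node ended up in.
#' @slot pbcs A \link[S4Vectors]{DataFrame} of clusters after decoupling:
#'   cluster_id (integer with optional letter suffix), contig, orf_begin,
#'   orf_end, span, n_nodes, sum_score, cluster_score, direction,
#'   decoupled_from, annotated, candidate and a \code{members} CharacterList.
#' @slot params Named list of thresholds (max_gap, score_low, score_high,
#'   min_nodes, score_mode).
#' @slot summary Named list of stage counts (n_components, n_ge_low,
#'   n_decoupled, n_ge_high, n_annotated).
#' @export
setClass("PBCSet",
  representation(nodes = "DataFrame", pbcs = "DataFrame",
                 params = "list", summary = "list"))

setValidity("PBCSet", function(object) {
  msg <- character()
  need <- c("cluster_id", "contig", "orf_begin", "orf_end", "n_nodes",
            "sum_score", "cluster_score", "direction", "annotated", "candidate")
  miss <- setdiff(need, names(object@pbcs))
  if (length(miss)) msg <- c(msg, paste("pbcs is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@pbcs) && any(object@pbcs$cluster_score < 0))
    msg <- c(msg, "cluster_score must be >= 0")
  if (length(msg)) msg else TRUE
})
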