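#' Construct a ProteomineExperiment
#'
#' Assembles spectral counts, protein lengths, an ORF map and a two-group
#' sample assignment into a validated [ProteomineExperiment-class] object.
#'
#' @param counts Integer matrix of spectral counts, proteins x samples, with
#'   rownames (protein IDs) and colnames (sample IDs).
#' @param lengths Integer vector of protein lengths in amino acids, one per
#'   protein (recycled against rownames of \code{counts} by position, or by
#'   name when named).
#' @param groups Named character vector or factor mapping each sample ID to
#'   one of exactly two group labels.
#' @param producing Label of the group representing the producing
#'   (nutrient-starved) state.
#' @param orfMap A data.frame with columns \code{protein_id},
#'   \code{orf_index}, \code{contig} and optionally \code{start}, \code{end},
#'   \code{strand}; must cover every protein in \code{counts}.
#' @return A [ProteomineExperiment-class].
#' @seealso [readCountTable()], [readOrfMap()], [computeNSAF()]
#' @export
ProteomineExperiment <- function(counts, lengths, groups, producing, orfMap) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have protein IDs as rownames and sample IDs as colnames")
  storage.mode(counts) <- "integer"
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("'lengths' must give one length per protein")
  groups <- as.character(groups[colnames(counts)])
  if (any(is.na(groups)))
    stop("'groups' must assign a group to every sample column")
  grps <- unique(groups)
  if (length(grps) != 2L)
    stop("exactly two distinct group labels are required, got: ",
         paste(grps, collapse = ", "))
  if (missing(producing) || !producing %in% grps)
    stop("'producing' must be one of: ", paste(grps, collapse = ", "))
  if (!all(c("protein_id", "orf_index", "contig") %in% names(orfMap)))
    stop("'orfMap' needs columns protein_id, orf_index, contig")
  idx <- match(rownames(counts), orfMap$protein_id)
  if (anyNA(idx))
    stop("ORF map is missing protein(s): ",
         paste(utils::head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
  om <- orfMap[idx, , drop = FALSE]
  rd <- S4Vectors::DataFrame(
    length = as.integer(lengths),
    orf_index = as.integer(om$orf_index),
    contig = as.character(om$contig))
  for (col in c("start", "end"))
    if (col %in% names(om)) rd[[col]] <- as.integer(om[[col]])
  if ("strand" %in% names(om)) rd$strand <- as.character(om$strand)
  rownames(rd) <- rownames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = rd,
    colData = S4Vectors::DataFrame(group = groups, row.names = colnames(counts)),
    metadata = list(producing = producing))
  methods::new("ProteomineExperiment", se, producing = producing)
}

#' Read a spectral-count table
#'
#' Reads a tab-separated protein quantification table with columns
#' \code{protein_id}, \code{length} and one integer column per sample.
#' Lines beginning with \code{#} are ignored.
#'
#' @param path Path to the TSV file.
#' @param groups Named character vector mapping every sample column to one of
#'   two group labels, or the path of a YAML group file (see
#'   [readGroupsFile()]).
#' @param producing The producing-group label; may be omitted when
#'   \code{groups} is a YAML file that names it.
#' @param orfMap An ORF map data.frame or file path (see [readOrfMap()]). If
#'   omitted, proteins are assigned consecutive ORF indices in file order on
#'   a single contig — only appropriate when the table is already in genome
#'   order.
#' @return A validated [ProteomineExperiment-class]; row order of the file is
#'   preserved.
#' @export
readCountTable <- function(path, groups, producing = NULL, orfMap = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("protein_id", "length"))
    if (!col %in% names(tab)) stop("count table is missing column '", col, "'")
  sampleCols <- setdiff(names(tab), c("protein_id", "length"))
  if (length(sampleCols) < 2L)
    stop("count table needs at least two sample columns")
  dup <- unique(tab$protein_id[duplicated(tab$protein_id)])
  if (length(dup))
    stop("duplicate protein ID(s) in count table: ", paste(dup, collapse = ", "))
  cnt <- as.matrix(tab[, sampleCols, drop = FALSE])
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid spectral count at protein '%s', sample '%s': %s",
                 tab$protein_id[bad[1, 1]], sampleCols[bad[1, 2]],
                 tab[[sampleCols[bad[1, 2]]]][bad[1, 1]]))
  rownames(cnt) <- tab$protein_id
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gf <- readGroupsFile(groups)
    groups <- gf$groups
    if (is.null(producing)) producing <- gf$producing
  }
  if (!all(sampleCols %in% names(groups)))
    stop("group assignment missing for sample(s): ",
         paste(setdiff(sampleCols, names(groups)), collapse = ", "))
  if (is.null(orfMap)) {
    orfMap <- data.frame(protein_id = tab$protein_id,
                         orf_index = seq_len(nrow(tab)),
                         contig = "contig_1", stringsAsFactors = FALSE)
  } else if (is.character(orfMap)) {
    orfMap <- readOrfMap(orfMap)
  }
  ProteomineExperiment(cnt, lengths = tab$length, groups = groups,
                       producing = producing, orfMap = orfMap)
}

#' Read an ORF map
#'
#' Reads the protein-to-genome map either from a TSV file with columns
#' \code{protein_id}, \code{orf_index}, \code{contig} (optionally
#' \code{start}, \code{end}, \code{strand}) or from a GFF3 file of CDS/gene
#' features, in which case ORF indices are assigned consecutively along the
#' assembly (contigs in order of appearance, features by start coordinate)
#' and the protein ID is taken from the \code{ID} attribute.
#'
#' @param path Path to the TSV or GFF3 file (\code{.gff}/\code{.gff3}).
#' @return A data.frame suitable for the \code{orfMap} argument of
#'   [ProteomineExperiment()].
#' @export
readOrfMap <- function(path) {
  if (!file.exists(path)) stop("ORF map not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type %in% c("CDS", "gene", "ORF")]
    if (length(gr) == 0L) stop("no CDS/gene/ORF features in GFF3: ", path)
    ord <- order(match(as.character(GenomicRanges::seqnames(gr)),
                       unique(as.character(GenomicRanges::seqnames(gr)))),
                 GenomicRanges::start(gr))
    gr <- gr[ord]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$locus_tag)
    if (is.null(ids) || anyNA(ids)) stop("GFF3 features lack ID attributes")
    out <- data.frame(protein_id = ids,
                      orf_index = seq_along(gr),
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("protein_id", "orf_index", "contig")
    miss <- setdiff(need, names(out))
    if (length(miss)) stop("ORF map is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(out$orf_index)) {
    d <- out$protein_id[out$orf_index %in% out$orf_index[duplicated(out$orf_index)]]
    stop("duplicate orf_index for proteins: ", paste(unique(d), collapse = ", "))
  }
  if ("start" %in% names(out)) {
    bad <- unlist(lapply(split(out, out$contig), function(ct) {
      ct <- ct[order(ct$orf_index), ]
      ct$protein_id[c(FALSE, diff(ct$start) <= 0)]
    }))
    if (length(bad))
      stop("orf_index is not increasing with genomic start within its ",
           "contig at: ", paste(bad, collapse = ", "))
  }
  out
}

#' Read a sample-group YAML file
#'
#' The file maps sample IDs to group labels under a \code{groups} key and
#' names the producing group under \code{producing}, e.g.
#' \preformatted{
#' groups:
#'   S1: growth
#'   S2: growth
#'   S3: starved
#'   S4: starved
#' producing: starved
#' }
#' A flat mapping without the \code{groups} key is also accepted.
#'
#' @param path Path to the YAML file.
#' @return List with \code{groups} (named character vector) and
#'   \code{producing} (label or NULL).
#' @export
readGroupsFile <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$groups)) {
    groups <- unlist(y$groups)
    producing <- y$producing
  } else {
    producing <- y$producing
    y$producing <- NULL
    groups <- unlist(y)
  }
  list(groups = groups, producing = producing)
}

## ---- accessors ----

#' Accessors for ProteomineExperiment
#'
#' @param x A [ProteomineExperiment-class].
#' @return \code{spectralCounts}: the integer count matrix. \code{nsaf}: the
#'   NSAF matrix (error if [computeNSAF()] has not been run).
#'   \code{proteinLengths}: named integer vector. \code{sampleGroups}: named
#'   character vector of group labels. \code{producingGroup} /
#'   \code{growthGroup}: the group labels. \code{orfIndex}, \code{contigId}:
#'   named vectors from the ORF map.
#' @name ProteomineExperiment-accessors
NULL

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("spectralCounts", "ProteomineExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("nsaf", "ProteomineExperiment", function(x) {
  if (!"nsaf" %in% SummarizedExperiment::assayNames(x))
    stop("no NSAF assay; run computeNSAF() first")
  SummarizedExperiment::assay(x, "nsaf")
})

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("proteinLengths", "ProteomineExperiment", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$length, rownames(x)))

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("sampleGroups", "ProteomineExperiment", function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x)))

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("producingGroup", "ProteomineExperiment", function(x) x@producing)

#' @rdname ProteomineExperiment-accessors
#' @export
growthGroup <- function(x) setdiff(unique(sampleGroups(x)), producingGroup(x))

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("orfIndex", "ProteomineExperiment", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$orf_index, rownames(x)))

#' @rdname ProteomineExperiment-accessors
#' @export
setMethod("contigId", "ProteomineExperiment", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$contig, rownames(x)))

setMethod("show", "ProteomineExperiment", function(object) {
  grp <- sampleGroups(object)
  cat("class: ProteomineExperiment\n")
  cat(sprintf("%d proteins x %d samples on %d contig(s)\n",
              nrow(object), ncol(object),
              length(unique(contigId(object)))))
  cat(sprintf("groups: %s (producing: %s)\n",
              paste(sprintf("%s (n=%d)", names(table(grp)), table(grp)),
                    collapse = ", "),
              producingGroup(object)))
  cat("assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  fl <- S4Vectors::metadata(object)$floor_value
  if (!is.null(fl)) cat(sprintf("imputation floor: %.4g\n", fl))
  sc <- SummarizedExperiment::rowData(object)$score
  if (!is.null(sc))
    cat(sprintf("scored nodes: %d of %d proteins (score != 0)\n",
                sum(sc != 0), nrow(object)))
  invisible(NULL)
})

## ---- NSAF ----

#' Compute NSAF abundances
#'
#' Converts spectral counts to normalized spectral abundance factors:
#' for protein \eqn{i} in a sample, \eqn{NSAF_i = (SpC_i / L_i) /
#' \sum_j (SpC_j / L_j)}, where \eqn{SpC} is the spectral count and \eqn{L}
#' the protein length. Per sample, NSAF over detected proteins sums to 1;
#' proteins with zero counts get NSAF 0 at this stage (floor imputation is a
#' separate step, [imputeAbundance()]).
#'
#' @param x A [ProteomineExperiment-class].
#' @param ... Unused.
#' @return \code{x} with an added \code{"nsaf"} assay.
#' @export
#' @rdname computeNSAF
setMethod("computeNSAF", "ProteomineExperiment", function(x, ...) {
  cnt <- spectralCounts(x)
  saf <- cnt / SummarizedExperiment::rowData(x)$length
  tot <- colSums(saf)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[tot == 0], collapse = ", "))
  SummarizedExperiment::assay(x, "nsaf") <- sweep(saf, 2, tot, "/")
  x
})

#' Detection filter and floor imputation
#'
#' Applies the detection rule: a protein is quantifiable in a sample group
#' only when its average spectral count over the group's replicates is at
#' least \code{minAvgSpC}. NSAF values of (protein, group) pairs that fail
#' the rule — and individual samples where the protein was not detected at
#' all — are assigned the floor value, one tenth of the lowest NSAF observed
#' across all samples of the comparison. Proteins failing the rule in both
#' groups are dropped entirely.
#'
#' After this step every abundance is strictly positive, so group means and
#' fold changes are always defined.
#'
#' @param x A [ProteomineExperiment-class] with an \code{"nsaf"} assay.
#' @param minAvgSpC Detection threshold on the group-average spectral count
#'   (default 3; the comparison is inclusive, \eqn{\ge}).
#' @param ... Unused.
#' @return The filtered \code{x}: dropped rows removed, \code{"nsaf"} assay
#'   floored, logical rowData columns \code{imputed_<group>} marking
#'   group-level imputation, and \code{metadata()$floor_value} set.
#' @export
#' @rdname imputeAbundance
setMethod("imputeAbundance", "ProteomineExperiment",
          function(x, minAvgSpC = 3, ...) {
  cnt <- spectralCounts(x)
  ns <- nsaf(x)
  grp <- sampleGroups(x)
  grps <- unique(grp)
  avg <- sapply(grps, function(g)
    rowMeans(cnt[, grp == g, drop = FALSE]))
  passes <- avg >= minAvgSpC                     # proteins x 2 groups
  keep <- rowSums(passes) > 0
  if (!any(keep)) stop("no quantifiable proteins: every protein fails the ",
                       "average spectral count threshold in both groups")
  minPos <- min(ns[ns > 0])
  floorValue <- minPos / 10
  ns[ns == 0] <- floorValue          # not detected in that sample
  for (g in grps) {
    fail <- !passes[, g]
    ns[fail, grp == g] <- floorValue # group below detection threshold
  }
  x <- x[keep, ]
  ns <- ns[keep, , drop = FALSE]
  SummarizedExperiment::assay(x, "nsaf") <- ns
  rd <- SummarizedExperiment::rowData(x)
  for (g in grps)
    rd[[paste0("imputed_", g)]] <- !passes[keep, g]
  SummarizedExperiment::rowData(x) <- rd
  S4Vectors::metadata(x)$floor_value <- floorValue
  S4Vectors::metadata(x)$min_avg_spc <- minAvgSpC
  x
})
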