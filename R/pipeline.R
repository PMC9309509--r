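## End-to-end orchestration: read inputs, run quant -> diffscore -> cluster,
## write deterministic report tables and a machine-readable summary.

.fmt <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x
}

.writeTSV <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
    df[[col]] <- .fmt(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the per-protein node table
#'
#' @param x A scored [ProteomineExperiment-class].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeNodeTable <- function(x, path) {
  .writeTSV(as.data.frame(nodeTable(x)), path)
}

#' Write a PBC table
#'
#' Columns: cluster_id, contig, orf_begin, orf_end, span, n_nodes,
#' sum_score, cluster_score, direction, decoupled_from and the
#' semicolon-joined member protein IDs.
#'
#' @param x A [PBCSet-class].
#' @param path Output TSV path.
#' @param which \code{"annotated"} (default), \code{"candidate"} or
#'   \code{"all"}.
#' @return The path, invisibly.
#' @export
writePBCTable <- function(x, path, which = c("annotated", "candidate", "all")) {
  which <- match.arg(which)
  tab <- switch(which, annotated = annotatedPBCs(x),
                candidate = candidatePBCs(x), all = pbcTable(x))
  df <- as.data.frame(tab[, setdiff(names(tab), "members")])
  df$member_protein_ids <- vapply(tab$members, paste, character(1),
                                  collapse = ";")
  .writeTSV(df, path)
}

#' Run the proteomining pipeline on files
#'
#' Reads a spectral-count table, a sample-group assignment and an ORF map,
#' runs NSAF quantification, detection filtering and imputation, node
#' scoring, proximity clustering with chimeric decoupling, and writes the
#' report files into \code{outDir}:
#' \itemize{
#'   \item \code{node_table.tsv} — every quantifiable protein with means,
#'     fold change, p-value and node score;
#'   \item \code{pbc_annotated.tsv} — annotated PBCs;
#'   \item \code{pbc_candidates.tsv} — the intermediate score band;
#'   \item \code{pbc_all.tsv} — every reported cluster incl. decoupled parts;
#'   \item \code{summary.yaml} — stage counts and every threshold used;
#'   \item optionally \code{pbc.bed}/\code{pbc.gff3} (when the ORF map has
#'     genomic coordinates) and \code{graph.dot}.
#' }
#' Output ordering (contig, then orf_begin) and numeric formatting
#' (6 significant digits) are fixed, so reruns with identical inputs are
#' byte-identical.
#'
#' @param counts Path to the count TSV (columns protein_id, length, one per
#'   sample).
#' @param orfMap Path to the ORF map TSV or GFF3.
#' @param groups Path to the YAML group file, or a named character vector.
#' @param producing Producing-group label (may come from the YAML file).
#' @param outDir Output directory (created if needed).
#' @param minAvgSpC,method,foldHigh,pHigh,foldLow,pLow,maxGap,scoreLow,scoreHigh,minNodes,scoreMode
#'   Thresholds, defaulting to the standard values; see [runProteomining()].
#' @param writeIntervals Write BED/GFF3 exports when coordinates are present
#'   (default TRUE).
#' @param writeDot Write the DOT graph export (default FALSE).
#' @param verbose Log one line per stage (default TRUE).
#' @return Invisibly, a list with \code{experiment}, \code{pbcs},
#'   \code{summary} and \code{files}.
#' @export
runPipeline <- function(counts, orfMap, groups, producing = NULL,
                        outDir = ".",
                        minAvgSpC = 3, method = "welch",
                        foldHigh = 2.0, pHigh = 0.01,
                        foldLow = 1.5, pLow = 0.05,
                        maxGap = 5, scoreLow = 1.5, scoreHigh = 3.0,
                        minNodes = 5, scoreMode = "span",
                        writeIntervals = TRUE, writeDot = FALSE,
                        verbose = TRUE) {
  log1 <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- "orf_map"
  res <- tryCatch({
    om <- if (is.character(orfMap)) readOrfMap(orfMap) else orfMap
    log1(stage, "%d ORFs on %d contig(s)", nrow(om), length(unique(om$contig)))
    stage <- "counts"
    pe <- readCountTable(counts, groups = groups, producing = producing,
                         orfMap = om)
    log1(stage, "%d proteins x %d samples", nrow(pe), ncol(pe))
    stage <- "quant"
    pe <- computeNSAF(pe)
    pe <- imputeAbundance(pe, minAvgSpC = minAvgSpC)
    log1(stage, "%d quantifiable proteins (floor %.4g)", nrow(pe),
         S4Vectors::metadata(pe)$floor_value)
    stage <- "diffscore"
    pe <- scoreNodes(pe, method = method, foldHigh = foldHigh, pHigh = pHigh,
                     foldLow = foldLow, pLow = pLow)
    nScored <- sum(SummarizedExperiment::rowData(pe)$score != 0)
    log1(stage, "%d scored nodes", nScored)
    stage <- "cluster"
    pbcs <- findPBCs(pe, maxGap = maxGap, scoreLow = scoreLow,
                     scoreHigh = scoreHigh, minNodes = minNodes,
                     scoreMode = scoreMode)
    s <- pbcSummary(pbcs)
    log1(stage, "%d clusters >= %.2g, %d annotated PBCs",
         s$n_ge_low, scoreLow, s$n_annotated)
    list(experiment = pe, pbcs = pbcs)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  pe <- res$experiment
  pbcs <- res$pbcs

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    node_table = file.path(outDir, "node_table.tsv"),
    pbc_annotated = file.path(outDir, "pbc_annotated.tsv"),
    pbc_candidates = file.path(outDir, "pbc_candidates.tsv"),
    pbc_all = file.path(outDir, "pbc_all.tsv"),
    summary = file.path(outDir, "summary.yaml"))
  writeNodeTable(pe, files["node_table"])
  writePBCTable(pbcs, files["pbc_annotated"], "annotated")
  writePBCTable(pbcs, files["pbc_candidates"], "candidate")
  writePBCTable(pbcs, files["pbc_all"], "all")

  summary <- c(pbcSummary(pbcs),
               list(n_proteins = nrow(pe), n_samples = ncol(pe),
                    producing_group = producingGroup(pe),
                    floor_value = S4Vectors::metadata(pe)$floor_value,
                    thresholds = list(
                      min_avg_spc = minAvgSpC, method = method,
                      fold_high = foldHigh, p_high = pHigh,
                      fold_low = foldLow, p_low = pLow,
                      max_gap = maxGap, score_low = scoreLow,
                      score_high = scoreHigh, min_nodes = minNodes,
                      score_mode = scoreMode)))
  yaml::write_yaml(summary, files["summary"])

  rd <- SummarizedExperiment::rowData(pe)
  if (writeIntervals && all(c("start", "end") %in% names(rd)) &&
      nrow(annotatedPBCs(pbcs)) > 0) {
    files["bed"] <- file.path(outDir, "pbc.bed")
    files["gff3"] <- file.path(outDir, "pbc.gff3")
    exportPBCIntervals(pbcs, files[["bed"]])
    exportPBCIntervals(pbcs, files[["gff3"]])
  }
  if (writeDot) {
    files["dot"] <- file.path(outDir, "graph.dot")
    exportGraphDOT(pbcs, files[["dot"]])
  }
  log1("report", "wrote %d file(s) to %s", length(files), outDir)
  invisible(list(experiment = pe, pbcs = pbcs, summary = summary,
                 files = files))
}

#' Write the NSAF abundance matrix
#'
#' Writes per-sample NSAF values with one \code{imputed_<group>} flag column
#' per group (TRUE where the whole group was floor-imputed).
#'
#' @param x A [ProteomineExperiment-class] after [imputeAbundance()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  impCols <- grep("^imputed_", names(rd), value = TRUE)
  if (!length(impCols))
    stop("no imputation flags; run imputeAbundance() first")
  df <- data.frame(protein_id = rownames(x), as.data.frame(nsaf(x)),
                   as.data.frame(rd[, impCols, drop = FALSE]),
                   check.names = FALSE)
  .writeTSV(df, path)
}

#' Write a simulated dataset to files
#'
#' Writes the counts TSV, ORF map TSV, group YAML and planted-truth TSV of a
#' [simulateProteomics()] result, in the formats [runPipeline()] reads.
#'
#' @param sim Result of [simulateProteomics()].
#' @param outDir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
writeSimulation <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pe <- sim$experiment
  cnt <- data.frame(protein_id = rownames(pe),
                    length = proteinLengths(pe),
                    spectralCounts(pe), check.names = FALSE)
  rd <- SummarizedExperiment::rowData(pe)
  om <- data.frame(protein_id = rownames(pe), orf_index = rd$orf_index,
                   contig = rd$contig)
  files <- c(counts = file.path(outDir, "counts.tsv"),
             orf_map = file.path(outDir, "orf_map.tsv"),
             groups = file.path(outDir, "groups.yaml"),
             truth = file.path(outDir, "truth.tsv"))
  .writeTSV(cnt, files["counts"])
  .writeTSV(om, files["orf_map"])
  yaml::write_yaml(list(groups = as.list(sampleGroups(pe)),
                        producing = producingGroup(pe)), files["groups"])
  .writeTSV(sim$truth, files["truth"])
  invisible(files)
}
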