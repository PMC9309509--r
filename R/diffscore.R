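## Per-protein differential expression between the producing and growth
## groups, and the two-tier signed node scores that feed the clustering.

## Vectorized two-sided Welch unequal-variance t-test over the rows of two
## matrices. Degenerate variance cases are resolved explicitly:
##   both groups constant & equal   -> p = 1 (no evidence of difference)
##   both groups constant & unequal -> p = 0 (limit of the t statistic as the
##                                     pooled variance vanishes; this is what
##                                     makes detected-in-one-group proteins,
##                                     floored to a constant in the other
##                                     group, maximally significant)
##   one group constant             -> ordinary Welch formula.
.welchRows <- function(xp, xg) {
  np <- ncol(xp); ng <- ncol(xg)
  mp <- rowMeans(xp); mg <- rowMeans(xg)
  vp <- rowSums((xp - mp)^2) / (np - 1)
  vg <- rowSums((xg - mg)^2) / (ng - 1)
  se2 <- vp / np + vg / ng
  tstat <- (mp - mg) / sqrt(se2)
  df <- se2^2 / ((vp / np)^2 / (np - 1) + (vg / ng)^2 / (ng - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  bothConst <- se2 == 0
  p[bothConst & mp == mg] <- 1
  p[bothConst & mp != mg] <- 0
  p
}

#' Assign the two-tier signed node score
#'
#' A protein becomes a scored node when it is differentially expressed:
#' 10 points when highly differential (fold-change magnitude >=
#' \code{foldHigh} and p <= \code{pHigh}), 5 points when moderately
#' differential (magnitude >= \code{foldLow} and p <= \code{pLow}),
#' 0 otherwise. The sign is positive for proteins up in the producing
#' (nutrient-starved) phase and negative for proteins expressed during the
#' growth phase. All boundary comparisons are inclusive.
#'
#' @param magnitude Fold-change magnitude, \code{pmax(fc, 1/fc)} (vector).
#' @param direction +1 (up in producing) or -1 (up in growth); 0 allowed for
#'   exactly equal means, which always yields score 0.
#' @param pValue Two-sided p-values in [0, 1]; \code{NA} (fold-change-only
#'   mode) waives the p-value condition.
#' @param foldHigh,pHigh Thresholds of the 10-point tier (defaults 2.0, 0.01).
#' @param foldLow,pLow Thresholds of the 5-point tier (defaults 1.5, 0.05).
#' @return Integer scores in \{-10, -5, 0, +5, +10\}.
#' @examples
#' assignNodeScore(2.5, +1, 0.005)   # +10
#' assignNodeScore(1.7, -1, 0.03)    # -5
#' assignNodeScore(2.0, +1, 0.03)    # +5: meets tier-2, misses tier-1 p
#' @export
assignNodeScore <- function(magnitude, direction, pValue,
                            foldHigh = 2.0, pHigh = 0.01,
                            foldLow = 1.5, pLow = 0.05) {
  stopifnot(all(magnitude >= 1 - 1e-12), all(is.na(pValue) | (pValue >= 0 & pValue <= 1)))
  pHighOK <- is.na(pValue) | pValue <= pHigh
  pLowOK <- is.na(pValue) | pValue <= pLow
  score <- ifelse(magnitude >= foldHigh & pHighOK, 10L,
           ifelse(magnitude >= foldLow & pLowOK, 5L, 0L))
  as.integer(score * sign(direction))
}

#' Score proteins as differential-expression nodes
#'
#' Computes, per protein, the group-mean NSAF abundances, the fold change
#' (producing over growth), its magnitude, a two-sided p-value, and the
#' signed node score of [assignNodeScore()]. Results are stored in
#' \code{rowData}.
#'
#' The p-value comes from a per-replicate two-sided Welch unequal-variance
#' t-test on NSAF values (\code{method = "welch"}, the default) or on
#' log2-NSAF (\code{method = "welch_log2"}). With a single replicate per
#' group no t-test is possible; \code{method = "fold_only"} then scores on
#' fold-change magnitude alone. A Benjamini-Hochberg adjusted column
#' (\code{p_adj}) is emitted for information only and never used in scoring.
#'
#' @param x A [ProteomineExperiment-class] after [imputeAbundance()].
#' @param method One of \code{"welch"}, \code{"welch_log2"},
#'   \code{"fold_only"}.
#' @param foldHigh,pHigh,foldLow,pLow Tier thresholds, see
#'   [assignNodeScore()].
#' @param ... Unused.
#' @return \code{x} with rowData columns \code{mean_producing},
#'   \code{mean_growth}, \code{fold_change}, \code{magnitude},
#'   \code{p_value}, \code{p_adj}, \code{score}.
#' @export
#' @rdname scoreNodes
setMethod("scoreNodes", "ProteomineExperiment",
          function(x, method = c("welch", "welch_log2", "fold_only"),
                   foldHigh = 2.0, pHigh = 0.01, foldLow = 1.5, pLow = 0.05,
                   ...) {
  method <- match.arg(method)
  ns <- nsaf(x)
  if (any(ns <= 0))
    stop("non-positive abundances present; run imputeAbundance() first")
  grp <- sampleGroups(x)
  prod <- producingGroup(x)
  xp <- ns[, grp == prod, drop = FALSE]
  xg <- ns[, grp != prod, drop = FALSE]
  if (method != "fold_only" && (ncol(xp) < 2L || ncol(xg) < 2L))
    stop("a t-test needs >= 2 replicates per group; ",
         "use method = \"fold_only\" for single-replicate designs")
  mp <- rowMeans(xp); mg <- rowMeans(xg)
  fc <- mp / mg
  magnitude <- pmax(fc, 1 / fc)
  p <- switch(method,
    welch = .welchRows(xp, xg),
    welch_log2 = .welchRows(log2(xp), log2(xg)),
    fold_only = rep(NA_real_, nrow(x)))
  direction <- sign(fc - 1)
  score <- assignNodeScore(magnitude, direction, p,
                           foldHigh = foldHigh, pHigh = pHigh,
                           foldLow = foldLow, pLow = pLow)
  rd <- SummarizedExperiment::rowData(x)
  rd$mean_producing <- mp
  rd$mean_growth <- mg
  rd$fold_change <- fc
  rd$magnitude <- magnitude
  rd$p_value <- p
  rd$p_adj <- if (method == "fold_only") NA_real_ else stats::p.adjust(p, "BH")
  rd$score <- score
  SummarizedExperiment::rowData(x) <- rd
  S4Vectors::metadata(x)$score_params <-
    list(method = method, fold_high = foldHigh, p_high = pHigh,
         fold_low = foldLow, p_low = pLow)
  x
})

#' Extract the node table
#'
#' @param x A scored [ProteomineExperiment-class] (after [scoreNodes()]).
#' @param scoredOnly Keep only proteins with score != 0 (default FALSE).
#' @param ... Unused.
#' @return A \link[S4Vectors]{DataFrame} with protein_id, orf_index, contig,
#'   mean_growth, mean_producing, fold_change, magnitude, p_value, p_adj and
#'   score, in genome order (contig, then orf_index).
#' @export
#' @rdname nodeTable
setMethod("nodeTable", "ProteomineExperiment", function(x, scoredOnly = FALSE, ...) {
  rd <- SummarizedExperiment::rowData(x)
  if (is.null(rd$score)) stop("no node scores; run scoreNodes() first")
  out <- S4Vectors::DataFrame(
    protein_id = rownames(x),
    orf_index = rd$orf_index,
    contig = rd$contig,
    mean_growth = rd$mean_growth,
    mean_producing = rd$mean_producing,
    fold_change = rd$fold_change,
    magnitude = rd$magnitude,
    p_value = rd$p_value,
    p_adj = rd$p_adj,
    score = rd$score)
  out <- out[order(match(out$contig, unique(out$contig)), out$orf_index), ]
  if (scoredOnly) out <- out[out$score != 0L, ]
  rownames(out) <- NULL
  out
})
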