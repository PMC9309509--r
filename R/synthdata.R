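## Seeded synthetic spectral-count datasets with planted BGC-like clusters,
## used to exercise and validate the whole pipeline without external data.

#' Default planted-cluster layout
#'
#' Six disjoint 10-ORF blocks, two per contig for a three-contig genome,
#' upregulated in the producing group at the given fold with the given
#' penetrance (fraction of members actually expressing the effect).
#'
#' @param nOrfs Total ORFs (default 3000).
#' @param nContigs Contigs (default 3); ORFs are split evenly.
#' @param blockSize ORFs per planted block (default 10).
#' @param fold Fold effect (default 8).
#' @param penetrance Fraction of block members expressing the effect
#'   (default 0.8).
#' @return A data.frame with columns contig, orf_start, orf_end, fold,
#'   direction, penetrance.
#' @export
defaultPlantedClusters <- function(nOrfs = 3000, nContigs = 3, blockSize = 10,
                                   fold = 8, penetrance = 0.8) {
  perContig <- nOrfs %/% nContigs
  starts <- unlist(lapply(seq_len(nContigs), function(ct) {
    off <- (ct - 1L) * perContig
    off + c(round(perContig * 0.25), round(perContig * 0.70))
  }))
  starts <- starts[seq_len(min(6L, length(starts)))]
  data.frame(contig = paste0("contig_", rep(seq_len(nContigs), each = 2L)[seq_along(starts)]),
             orf_start = starts,
             orf_end = starts + blockSize - 1L,
             fold = fold,
             direction = "producing",
             penetrance = penetrance,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group spectral-count dataset
#'
#' Emulates a producing-versus-growth label-free proteomics comparison over
#' an ordered ORF list: background proteins draw negative-binomial spectral
#' counts with identical expected value in both groups; members of planted
#' clusters have their expected count multiplied by the fold effect in the
#' designated group; each (protein, sample) cell is independently zeroed
#' with the dropout probability, mimicking non-detection. Fully
#' deterministic given \code{seed}.
#'
#' @param nOrfs Number of ORFs/proteins (default 3000).
#' @param nContigs Number of contigs; ORFs are split evenly and indexed
#'   consecutively across the whole assembly (default 3).
#' @param replicates Replicates per group (default 3, used for both groups;
#'   a length-2 vector gives growth and producing counts separately).
#' @param mu Background negative-binomial mean spectral count (default 20).
#' @param size Negative-binomial size (dispersion) parameter; variance is
#'   \eqn{\mu + \mu^2/size} (default 5).
#' @param dropout Per-(protein, sample) probability of a missed detection
#'   (default 0.1).
#' @param planted Planted-cluster data.frame as from
#'   [defaultPlantedClusters()] (the default), or NULL/zero rows for a null
#'   dataset. Columns: contig, orf_start, orf_end, fold (>= 1), direction
#'   ("producing" or "growth"), penetrance in [0, 1]. Ranges must be
#'   disjoint and within their contig.
#' @param lengthRange Uniform integer range of protein lengths in amino
#'   acids (default c(100, 1000)).
#' @param seed Integer seed driving all randomness.
#' @return A list with \code{experiment} (a [ProteomineExperiment-class];
#'   groups "growth"/"producing", producing group "producing"),
#'   \code{truth} (data.frame of planted blocks with a \code{planted_id})
#'   and \code{members} (data.frame: protein_id, orf_index, planted_id,
#'   expressing — per-protein true differential status).
#' @export
simulateProteomics <- function(nOrfs = 3000, nContigs = 3, replicates = 3,
                               mu = 20, size = 5, dropout = 0.1,
                               planted = defaultPlantedClusters(nOrfs, nContigs),
                               lengthRange = c(100, 1000), seed = 1) {
  stopifnot(nOrfs >= 1, nContigs >= 1, mu > 0, size > 0,
            dropout >= 0, dropout <= 1)
  if (length(replicates) == 1L) replicates <- rep(replicates, 2L)
  nG <- replicates[1]; nP <- replicates[2]
  if (is.null(planted)) planted <- defaultPlantedClusters(nOrfs, nContigs)[0, ]
  if (nrow(planted)) {
    stopifnot(all(planted$fold >= 1),
              all(planted$penetrance >= 0 & planted$penetrance <= 1),
              all(planted$orf_start >= 1), all(planted$orf_end <= nOrfs),
              all(planted$orf_end >= planted$orf_start))
    iv <- planted[order(planted$orf_start), ]
    if (any(iv$orf_start[-1] <= iv$orf_end[-nrow(iv)]))
      stop("planted cluster ranges overlap")
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  perContig <- rep(nOrfs %/% nContigs, nContigs)
  perContig[nContigs] <- perContig[nContigs] + nOrfs %% nContigs
  contig <- rep(paste0("contig_", seq_len(nContigs)), perContig)
  orfIdx <- seq_len(nOrfs)
  proteinIds <- sprintf("ORF%05d", orfIdx)
  lengths <- sample(lengthRange[1]:lengthRange[2], nOrfs, replace = TRUE)

  samples <- c(paste0("growth_", seq_len(nG)), paste0("producing_", seq_len(nP)))
  groups <- stats::setNames(rep(c("growth", "producing"), c(nG, nP)), samples)

  ## expected count per (protein, group)
  muMat <- matrix(mu, nOrfs, 2, dimnames = list(NULL, c("growth", "producing")))
  members <- data.frame(protein_id = character(), orf_index = integer(),
                        planted_id = integer(), expressing = logical(),
                        stringsAsFactors = FALSE)
  if (nrow(planted)) {
    planted$planted_id <- seq_len(nrow(planted))
    for (b in seq_len(nrow(planted))) {
      rng <- planted$orf_start[b]:planted$orf_end[b]
      if (length(unique(contig[rng])) != 1L ||
          contig[rng][1] != planted$contig[b])
        stop("planted range ", b, " does not lie within contig ",
             planted$contig[b])
      nExpr <- round(planted$penetrance[b] * length(rng))
      expressing <- rng[sort(sample(seq_along(rng), nExpr))]
      g <- planted$direction[b]
      muMat[expressing, g] <- muMat[expressing, g] * planted$fold[b]
      members <- rbind(members, data.frame(
        protein_id = proteinIds[rng], orf_index = rng,
        planted_id = b, expressing = rng %in% expressing,
        stringsAsFactors = FALSE))
    }
  }

  counts <- matrix(0L, nOrfs, nG + nP, dimnames = list(proteinIds, samples))
  for (s in seq_along(samples)) {
    g <- groups[s]
    counts[, s] <- stats::rnbinom(nOrfs, mu = muMat[, g], size = size)
  }
  if (dropout > 0) {
    drop <- matrix(stats::runif(length(counts)) < dropout,
                   nrow(counts), ncol(counts))
    counts[drop] <- 0L
  }

  orfMap <- data.frame(protein_id = proteinIds, orf_index = orfIdx,
                       contig = contig, stringsAsFactors = FALSE)
  pe <- ProteomineExperiment(counts, lengths = lengths, groups = groups,
                             producing = "producing", orfMap = orfMap)
  S4Vectors::metadata(pe)$simulation <- list(
    seed = as.integer(seed), mu = mu, size = size, dropout = dropout,
    replicates = c(growth = nG, producing = nP))
  truth <- if (nrow(planted)) planted else
    cbind(planted, planted_id = integer(0))
  list(experiment = pe, truth = truth, members = members)
}

#' Run the full pipeline on a ProteomineExperiment
#'
#' Convenience composition quant -> diffscore -> cluster with the standard
#' defaults: [computeNSAF()], [imputeAbundance()], [scoreNodes()],
#' [findPBCs()]. Any threshold can be overridden via the named arguments of
#' those functions.
#'
#' @param x A [ProteomineExperiment-class] with raw counts.
#' @param minAvgSpC Detection threshold (default 3).
#' @param method p-value method, see [scoreNodes()].
#' @param foldHigh,pHigh,foldLow,pLow Node-score tiers.
#' @param maxGap,scoreLow,scoreHigh,minNodes,scoreMode Clustering thresholds,
#'   see [findPBCs()].
#' @return A list with \code{experiment} (the scored
#'   [ProteomineExperiment-class]) and \code{pbcs} (the [PBCSet-class]).
#' @export
runProteomining <- function(x, minAvgSpC = 3,
                            method = "welch",
                            foldHigh = 2.0, pHigh = 0.01,
                            foldLow = 1.5, pLow = 0.05,
                            maxGap = 5, scoreLow = 1.5, scoreHigh = 3.0,
                            minNodes = 5, scoreMode = "span") {
  x <- computeNSAF(x)
  x <- imputeAbundance(x, minAvgSpC = minAvgSpC)
  x <- scoreNodes(x, method = method, foldHigh = foldHigh, pHigh = pHigh,
                  foldLow = foldLow, pLow = pLow)
  pbcs <- findPBCs(x, maxGap = maxGap, scoreLow = scoreLow,
                   scoreHigh = scoreHigh, minNodes = minNodes,
                   scoreMode = scoreMode)
  list(experiment = x, pbcs = pbcs)
}

#' Evaluate recovery of planted clusters
#'
#' Matches annotated PBCs against the planted truth of a synthetic dataset.
#' A planted block is recovered when some annotated PBC has at least
#' \code{minOverlap} of its member nodes inside the block's ORF range (same
#' contig). Annotated PBCs whose members hit no planted block are counted as
#' false positives.
#'
#' @param pbcSet A [PBCSet-class] from the synthetic experiment.
#' @param truth Planted-cluster data.frame from [simulateProteomics()].
#' @param minOverlap Minimum fraction of PBC member nodes inside the block
#'   (default 0.8).
#' @return A list with \code{recovered} (logical per planted block),
#'   \code{n_recovered}, \code{n_planted}, \code{false_positives} (number of
#'   annotated PBCs overlapping no planted block) and \code{n_annotated}.
#' @export
evaluateRecovery <- function(pbcSet, truth, minOverlap = 0.8) {
  ann <- annotatedPBCs(pbcSet)
  nodes <- as.data.frame(pbcNodes(pbcSet))
  nPlanted <- nrow(truth)
  recovered <- logical(nPlanted)
  fp <- 0L
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      m <- nodes[match(ann$members[[i]], nodes$protein_id), , drop = FALSE]
      hitAny <- FALSE
      for (b in seq_len(nPlanted)) {
        inBlock <- m$contig == truth$contig[b] &
          m$orf_index >= truth$orf_start[b] & m$orf_index <= truth$orf_end[b]
        if (any(inBlock)) hitAny <- TRUE
        if (mean(inBlock) >= minOverlap) recovered[b] <- TRUE
      }
      if (!hitAny) fp <- fp + 1L
    }
  }
  list(recovered = recovered, n_recovered = sum(recovered),
       n_planted = nPlanted, false_positives = fp, n_annotated = nrow(ann))
}

#' Null false-positive rate of annotated PBCs
#'
#' Simulates datasets with no planted effects (both groups drawn from the
#' same background model), runs the full pipeline on each, and reports the
#' number of annotated PBCs per simulation — an empirical false-discovery
#' check of the clustering thresholds.
#'
#' @param nSims Number of simulations (default 20).
#' @param seed Base seed; simulation \eqn{i} uses \code{seed + i - 1}.
#' @param nOrfs,nContigs,replicates,mu,size,dropout Generator settings, see
#'   [simulateProteomics()].
#' @param ... Threshold overrides passed to [runProteomining()].
#' @return A list with \code{counts} (annotated PBCs per simulation) and
#'   \code{mean}.
#' @export
nullPBCRate <- function(nSims = 20, seed = 1, nOrfs = 3000, nContigs = 3,
                        replicates = 3, mu = 20, size = 5, dropout = 0.1,
                        ...) {
  stopifnot(nSims >= 1)
  counts <- vapply(seq_len(nSims), function(i) {
    sim <- simulateProteomics(nOrfs = nOrfs, nContigs = nContigs,
                              replicates = replicates, mu = mu, size = size,
                              dropout = dropout, planted = NULL,
                              seed = seed + i - 1L)
    res <- runProteomining(sim$experiment, ...)
    pbcSummary(res$pbcs)$n_annotated
  }, numeric(1))
  list(counts = counts, mean = mean(counts))
}
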