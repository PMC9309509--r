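# NSAF quantification: table parsing, normalization, detection filter and
# floor imputation.

test_that("a well-formed count table round-trips through readCountTable", {
  df <- data.frame(protein_id = c("A", "B", "C"), length = c(100L, 300L, 250L),
                   g1 = c(4L, 0L, 7L), g2 = c(5L, 1L, 6L), g3 = c(3L, 2L, 9L),
                   p1 = c(10L, 8L, 1L), p2 = c(12L, 9L, 0L), p3 = c(11L, 7L, 2L))
  path <- writeCountTSV(df)
  groups <- setNames(rep(c("growth", "producing"), each = 3),
                     c("g1", "g2", "g3", "p1", "p2", "p3"))
  pe <- readCountTable(path, groups = groups, producing = "producing")
  expect_s4_class(pe, "ProteomineExperiment")
  expect_identical(rownames(pe), c("A", "B", "C"))   # row order preserved
  expect_identical(unname(proteinLengths(pe)), c(100L, 300L, 250L))
  expect_identical(sort(unique(sampleGroups(pe))), c("growth", "producing"))
  expect_identical(producingGroup(pe), "producing")
  expect_identical(spectralCounts(pe)["C", "p2"], 0L)
})

test_that("malformed count tables are rejected with the offending cell named", {
  base <- data.frame(protein_id = c("A", "B"), length = c(100L, 200L),
                     s1 = c(1L, 2L), s2 = c(3L, 4L))
  groups <- c(s1 = "growth", s2 = "producing")

  neg <- base; neg$s2[1] <- -1L
  expect_error(readCountTable(writeCountTSV(neg), groups, "producing"),
               "protein 'A', sample 's2'")

  dup <- rbind(base, base[1, ])
  expect_error(readCountTable(writeCountTSV(dup), groups, "producing"),
               "duplicate protein ID.*A")

  nolen <- base[, setdiff(names(base), "length")]
  expect_error(readCountTable(writeCountTSV(nolen), groups, "producing"),
               "missing column 'length'")

  expect_error(readCountTable(writeCountTSV(base), c(s1 = "growth"), "growth"),
               "missing for sample")
})

test_that("NSAF matches hand-computed values and normalizes per sample", {
  # A: SpC 10, L 100 (SAF 0.1); B: SpC 30, L 300 (SAF 0.1) -> 0.5 / 0.5
  pe <- makePE(matrix(c(10L, 30L, 10L, 30L, 10L, 30L, 10L, 30L), 2,
                      dimnames = list(c("A", "B"), NULL)),
               lengths = c(100L, 300L))
  pe <- computeNSAF(pe)
  expect_equal(unname(nsaf(pe)[, 1]), c(0.5, 0.5))

  # A: SpC 20, L 100 (SAF 0.2); B: SpC 10, L 200 (SAF 0.05) -> 0.8 / 0.2
  pe2 <- makePE(matrix(c(20L, 10L), 2, 4, dimnames = list(c("A", "B"), NULL)),
                lengths = c(100L, 200L))
  pe2 <- computeNSAF(pe2)
  expect_equal(unname(nsaf(pe2)[, 3]), c(0.8, 0.2))

  # single detected protein normalizes to 1 regardless of count and length
  pe3 <- makePE(matrix(7L, 1, 4, dimnames = list("A", NULL)),
                lengths = 200L)
  expect_equal(unname(nsaf(computeNSAF(pe3))[1, ]), rep(1, 4))
})

test_that("an all-zero sample column is reported by name", {
  cnt <- matrix(c(1L, 2L, 0L, 0L, 3L, 4L, 5L, 6L), 2,
                dimnames = list(c("A", "B"), c("s1", "s2", "s3", "s4")))
  expect_error(computeNSAF(makePE(cnt)), "all-zero counts.*s2")
})

test_that("detection threshold is inclusive and floors follow the lowest NSAF", {
  # protein D: growth counts (2,3,4), average exactly 3 -> passes (>=)
  # protein U: undetected in growth -> floored there
  cnt <- rbind(A = c(50L, 50L, 50L, 50L, 50L, 50L),
               D = c(2L, 3L, 4L, 9L, 9L, 9L),
               U = c(0L, 0L, 0L, 40L, 44L, 42L))
  colnames(cnt) <- c("g1", "g2", "g3", "p1", "p2", "p3")
  pe <- computeNSAF(makePE(cnt))
  preNSAF <- nsaf(pe)
  pe <- imputeAbundance(pe, minAvgSpC = 3)
  rd <- SummarizedExperiment::rowData(pe)
  expect_false(rd["D", "imputed_growth"])
  expect_true(rd["U", "imputed_growth"])
  expect_false(rd["U", "imputed_producing"])
  # floor = (global minimum positive NSAF) / 10, recomputed independently
  expectedFloor <- min(preNSAF[preNSAF > 0]) / 10
  expect_identical(S4Vectors::metadata(pe)$floor_value, expectedFloor)
  expect_equal(unname(nsaf(pe)["U", c("g1", "g2", "g3")]),
               rep(expectedFloor, 3))
  # imputed values never reach any observed NSAF
  expect_lt(expectedFloor, min(preNSAF[preNSAF > 0]))
})

test_that("proteins failing detection in both groups are dropped", {
  cnt <- rbind(A = c(50L, 50L, 50L, 50L, 50L, 50L),
               Z = c(1L, 0L, 1L, 0L, 1L, 0L))   # avg < 3 in both groups
  colnames(cnt) <- paste0("s", 1:6)
  pe <- imputeAbundance(computeNSAF(makePE(cnt)))
  expect_identical(rownames(pe), "A")
  # and when nothing passes anywhere, the run aborts
  cntAll <- rbind(Z = c(1L, 0L, 1L, 0L, 1L, 0L),
                  Y = c(0L, 1L, 0L, 1L, 0L, 1L))
  colnames(cntAll) <- paste0("s", 1:6)
  expect_error(imputeAbundance(computeNSAF(makePE(cntAll))),
               "no quantifiable proteins")
})

test_that("NSAF properties hold over random count matrices", {
  set.seed(421)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    m <- sample(4:8, 1)
    cnt <- matrix(rpois(n * m, 8), n, m,
                  dimnames = list(paste0("P", 1:n), paste0("S", 1:m)))
    storage.mode(cnt) <- "integer"
    cnt[1, ] <- pmax(cnt[1, ], 1L)        # no all-zero sample
    pe <- computeNSAF(makePE(cnt))
    ns <- nsaf(pe)
    # per-sample normalization
    expect_true(all(abs(colSums(ns) - 1) < 1e-9))
    # scaling one sample's counts by a positive integer leaves NSAF unchanged
    cnt2 <- cnt; cnt2[, 1] <- cnt2[, 1] * 7L
    ns2 <- nsaf(computeNSAF(makePE(cnt2)))
    expect_equal(ns2[, 1], ns[, 1], tolerance = 1e-12)
    # imputation: output proteins = input minus both-group failures, no dups
    peI <- imputeAbundance(pe)
    grp <- sampleGroups(pe)
    avg <- sapply(unique(grp), function(g)
      rowMeans(cnt[, grp == g, drop = FALSE]))
    keep <- rownames(cnt)[rowSums(avg >= 3) > 0]
    expect_identical(rownames(peI), keep)
    expect_false(anyDuplicated(rownames(peI)) > 0)
    expect_true(all(nsaf(peI) > 0))
  }
})

test_that("ORF maps must increase with genomic position within a contig", {
  om <- data.frame(protein_id = c("A", "B", "C"), orf_index = 1:3,
                   contig = "c1", start = c(100L, 900L, 500L),
                   end = c(400L, 1200L, 800L))
  path <- tempfile(fileext = ".tsv")
  write.table(om, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readOrfMap(path), "not increasing.*C")
  om$start <- c(100L, 500L, 900L); om$end <- c(400L, 800L, 1200L)
  write.table(om, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readOrfMap(path)$protein_id, c("A", "B", "C"))
})

test_that("the NSAF export carries values and per-group imputation flags", {
  cnt <- rbind(A = c(50L, 50L, 50L, 50L, 50L, 50L),
               U = c(0L, 0L, 0L, 40L, 44L, 42L))
  colnames(cnt) <- paste0("s", 1:6)
  pe <- imputeAbundance(computeNSAF(makePE(cnt)))
  path <- tempfile(fileext = ".tsv")
  writeAbundanceTable(pe, path)
  tab <- read.delim(path)
  expect_identical(tab$protein_id, c("A", "U"))
  expect_true(all(c("imputed_growth", "imputed_producing") %in% names(tab)))
  expect_true(tab$imputed_growth[tab$protein_id == "U"])
  expect_equal(tab$s4[2], signif(nsaf(pe)["U", "s4"], 6))
})
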