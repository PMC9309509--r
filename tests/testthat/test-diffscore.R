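# Fold changes, Welch p-values (with degenerate-variance rules) and the
# two-tier signed node scores.

# exact abundance fixture: rows are proteins, first 3 columns growth,
# last 3 producing
abund <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("g1", "g2", "g3", "p1", "p2", "p3")
  m
}

test_that("fold change and magnitude come from group-mean abundances", {
  ns <- abund(
    up   = c(0.001, 0.001, 0.001, 0.004, 0.004, 0.004),  # fc 4
    down = c(0.004, 0.004, 0.004, 0.001, 0.001, 0.001),  # fc 0.25
    flat = c(0.002, 0.002, 0.002, 0.002, 0.002, 0.002))  # fc 1
  pe <- scoreNodes(makeScoredInput(ns))
  rd <- SummarizedExperiment::rowData(pe)
  expect_equal(unname(rd$fold_change), c(4, 0.25, 1))
  expect_equal(unname(rd$magnitude), c(4, 4, 1))
  expect_identical(unname(rd["flat", "score"]), 0L)
})

test_that("degenerate variance cases follow the stated limits", {
  ns <- abund(
    same  = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01),   # identical -> p = 1
    shift = c(0.01, 0.01, 0.01, 0.03, 0.03, 0.03))   # two constants -> p = 0
  rd <- SummarizedExperiment::rowData(scoreNodes(makeScoredInput(ns)))
  expect_equal(unname(rd["same", "p_value"]), 1)
  expect_equal(unname(rd["shift", "p_value"]), 0)
  # the constant-vs-constant limit is what makes a protein detected only in
  # one group (other group floored) a strong node
  expect_identical(unname(rd["shift", "score"]), 10L)
})

test_that("Welch p-values agree with stats::t.test as independent oracle", {
  # the textbook case: clearly separated tight groups
  x <- c(0.010, 0.012, 0.011); y <- c(0.001, 0.002, 0.001)
  ns <- abund(p = c(y, x))
  rd <- SummarizedExperiment::rowData(scoreNodes(makeScoredInput(ns)))
  expect_lt(rd["p", "p_value"], 0.01)
  expect_equal(unname(rd["p", "p_value"]), t.test(x, y)$p.value, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:25) {
    g <- abs(rnorm(3, 0.01, 0.004)) + 1e-6
    p <- abs(rnorm(3, 0.02, 0.008)) + 1e-6
    ns <- abund(p = c(g, p))
    rd <- SummarizedExperiment::rowData(scoreNodes(makeScoredInput(ns)))
    expect_equal(unname(rd["p", "p_value"]), t.test(p, g)$p.value, tolerance = 1e-10)
  }
})

test_that("single-replicate designs require fold-change-only mode", {
  cnt <- matrix(c(10L, 20L, 30L, 5L), 2,
                dimnames = list(c("A", "B"), c("g1", "p1")))
  pe <- imputeAbundance(computeNSAF(
    makePE(cnt, groups = c(g1 = "growth", p1 = "producing"))))
  expect_error(scoreNodes(pe, method = "welch"), "fold_only")
  rd <- SummarizedExperiment::rowData(scoreNodes(pe, method = "fold_only"))
  expect_true(all(is.na(rd$p_value)))
  expect_true(all(rd$score != 0))   # scores on magnitude alone
})

test_that("node scores match the worked tier examples", {
  expect_identical(assignNodeScore(2.5, +1, 0.005), 10L)
  expect_identical(assignNodeScore(1.7, -1, 0.03), -5L)
  expect_identical(assignNodeScore(1.4, +1, 0.0001), 0L)
  expect_identical(assignNodeScore(2.0, +1, 0.03), 5L)  # tier-2 only
})

test_that("tier logic matches a brute-force truth table over all regions", {
  oracle <- function(mag, dir, p) {
    s <- if (mag >= 2.0 && p <= 0.01) 10
         else if (mag >= 1.5 && p <= 0.05) 5
         else 0
    as.integer(s * sign(dir))
  }
  mags <- c(1, 1.2, 1.5, 1.7, 2.0, 2.5, 10)     # straddle both fold cutoffs
  ps <- c(0, 0.005, 0.01, 0.03, 0.05, 0.2, 1)   # straddle both p cutoffs
  for (mag in mags) for (p in ps) for (dir in c(-1, 1))
    expect_identical(assignNodeScore(mag, dir, p), oracle(mag, dir, p))
})

test_that("swapping group labels negates scores and inverts fold changes", {
  set.seed(99)
  cnt <- matrix(rpois(60, 20), 10, 6,
                dimnames = list(paste0("P", 1:10), paste0("S", 1:6)))
  storage.mode(cnt) <- "integer"
  groups <- setNames(rep(c("growth", "producing"), each = 3), colnames(cnt))
  run <- function(producing)
    SummarizedExperiment::rowData(scoreNodes(imputeAbundance(computeNSAF(
      makePE(cnt, groups = groups, producing = producing)))))
  a <- run("producing")
  b <- run("growth")
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
  expect_identical(a$score, -b$score)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("p-values are invariant to rescaling all abundances", {
  set.seed(5)
  base <- matrix(abs(rnorm(30, 0.01, 0.005)) + 1e-5, 5, 6)
  colnames(base) <- c("g1", "g2", "g3", "p1", "p2", "p3")
  rownames(base) <- paste0("P", 1:5)
  p1 <- SummarizedExperiment::rowData(scoreNodes(makeScoredInput(base)))$p_value
  p2 <- SummarizedExperiment::rowData(scoreNodes(makeScoredInput(base * 37)))$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
})
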