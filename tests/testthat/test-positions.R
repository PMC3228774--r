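test_that("deletePosition excises exactly one position and keeps labels", {
  ps <- PeptideSet(c("LLFGYPVYV", "GILGFVFTL"), c(1, -1))
  d6 <- deletePosition(ps, 6)
  expect_identical(as.character(d6), c("LLFGYVYV", "GILGFFTL"))
  expect_identical(labels(d6), labels(ps))
  expect_identical(length(d6), 2L)
  # repeated deletion at the boundary positions
  d11 <- deletePosition(deletePosition(ps, 1), 1)
  expect_identical(peptideLength(d11), 7L)
  expect_identical(as.character(deletePosition(ps, 9))[1], "LLFGYPVY")
  expect_error(deletePosition(ps, 0), "pos")
  expect_error(deletePosition(ps, 10), "pos")
})

test_that("position importance pinpoints the planted position", {
  ds <- makeRuleData(n = 100, seed = 19)
  imp <- positionImportance(ds, nRuns = 2, seed = 23,
                            grid = gridSpec(C = 1, d = 9))
  expect_identical(imp$position, 1:9)
  expect_identical(which.max(imp$deltaMCC), 4L)
  others <- imp$deltaMCC[imp$position != 4]
  expect_gte(imp$deltaMCC[4] - max(others), 0.2)
  expect_true(imp$important[4])
  # delta is definitionally baseline minus deleted
  expect_equal(imp$deltaMCC, imp$baselineMCC - imp$deletedMCC,
               tolerance = 1e-12)
})

test_that("position importance stays near zero without sequence signal", {
  null <- generateDataset(50, 50, motif = motifSpec(), seed = 29)
  imp <- positionImportance(null, nRuns = 1, seed = 31,
                            grid = gridSpec(C = 1, d = 9))
  expect_true(all(abs(imp$deltaMCC) <= 0.25))
  expect_equal(mean(imp$deltaMCC), 0, tolerance = 0.1)
})

test_that("two-sample logo flags a planted enrichment after Bonferroni", {
  pos <- generateDataset(200, 0, motif = motifSpec(4, "G", 0.8, 0),
                         seed = 41)
  neg <- generateDataset(0, 200, motif = motifSpec(4, "G", 0, 0.05),
                         seed = 43)
  lg <- twoSampleLogo(pos, neg)
  expect_identical(attr(lg, "m"), 180L)  # 9 positions x 20 residues
  g4 <- lg[lg$position == 4 & lg$symbol == "G", ]
  expect_true(g4$significant)
  expect_identical(g4$direction, "over")
  expect_lt(g4$p, 0.05 / 180)
  expect_gt(g4$freqPos, g4$freqNeg)
  # an unplanted symbol at another position is not flagged
  expect_false(any(lg$significant & lg$position == 5 & lg$symbol == "W"))
})

test_that("identical input sets produce zero flags and swap antisymmetry holds", {
  set.seed(47)
  a <- randomPeptides(80)
  b <- randomPeptides(80)
  same <- twoSampleLogo(a, a)
  expect_false(any(same$significant))
  expect_true(all(same$p == 1 | !same$significant))
  fwd <- twoSampleLogo(a, b)
  rev <- twoSampleLogo(b, a)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  expect_equal(fwd$t, -rev$t, tolerance = 1e-12)
  over <- fwd$direction == "over"
  expect_identical(rev$direction[over], rep("under", sum(over)))
  expect_error(twoSampleLogo(character(0), a), "non-empty")
  expect_error(twoSampleLogo(a, randomPeptides(5, L = 8)), "length")
})

test_that("the indicator t-test matches stats::t.test to high precision", {
  set.seed(53)
  for (var.equal in c(FALSE, TRUE)) {
    for (rep in 1:10) {
      n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
      x1 <- sample(c(0, 1), n1, replace = TRUE)
      x2 <- sample(c(0, 1), n2, replace = TRUE)
      if (stats::var(x1) == 0 && stats::var(x2) == 0) next
      mine <- tcreact:::indicatorTTest(x1, x2, var.equal = var.equal)
      ref <- stats::t.test(x1, x2, var.equal = var.equal)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  }
  # both-sets-constant degenerate case is p = 1, not an error
  deg <- tcreact:::indicatorTTest(rep(0, 5), rep(0, 7))
  expect_identical(deg$p, 1)
})

test_that("flags strengthen with sample size at fixed effect", {
  flagAt <- function(n) {
    pos <- generateDataset(n, 0, motif = motifSpec(4, "G", 0.8, 0),
                           seed = 100 + n)
    neg <- generateDataset(0, n, motif = motifSpec(4, "G", 0, 0.05),
                           seed = 200 + n)
    lg <- twoSampleLogo(pos, neg)
    lg$significant[lg$position == 4 & lg$symbol == "G"]
  }
  flags <- vapply(c(50, 100, 200), flagAt, logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))  # never un-flags
  expect_true(flags[3])
})

test_that("S/M/L recoding follows the thresholds and preserves structure", {
  ps <- PeptideSet(c("GILGFVFTL", "LLFGYPVYV"), c(1, -1))
  rec <- recodeAlphabet(ps, "vdw_volume")
  expect_identical(peptideLength(rec), 9L)
  expect_identical(labels(rec), labels(ps))
  # glycine has the smallest normalized volume: class S
  expect_identical(substr(as.character(rec)[1], 1, 4), "SMMS")
  # hydrophobicity classes under the 0.5/2.5 thresholds
  rech <- recodeAlphabet(PeptideSet("AIDS", 1), "hydrophobicity")
  expect_identical(as.character(rech), "MLSS")
  # custom scales need thresholds
  expect_error(recodeAlphabet(ps, "x", values = c(A = 1)), "thresholds")
  expect_error(recodeAlphabet(ps, "x", values = c(A = 1),
                              thresholds = c(0, 1)), "missing")
})

test_that("property logos detect planted class structure and ignore residue identity", {
  # positives carry small-volume residues at position 5, negatives large
  set.seed(61)
  mkset <- function(res, n) {
    base <- randomPeptides(n)
    substr(base, 5, 5) <- sample(res, n, replace = TRUE)
    base
  }
  small <- c("G", "A", "S")   # vdw volume < 2.0
  large <- c("W", "Y", "R")   # vdw volume >= 6.0
  ds <- PeptideSet(c(mkset(small, 120), mkset(large, 120)),
                   rep(c(1, -1), each = 120))
  lg <- propertyLogo(ds, "vdw_volume")
  expect_identical(attr(lg, "m"), 27L)  # 9 positions x 3 classes
  s5 <- lg[lg$position == 5 & lg$symbol == "S", ]
  expect_true(s5$significant)
  expect_identical(s5$direction, "over")
  # swapping which residue realizes the class changes nothing
  ds2 <- PeptideSet(c(mkset(rev(small), 120), mkset(rev(large), 120)),
                    rep(c(1, -1), each = 120))
  lg2 <- propertyLogo(ds2, "vdw_volume")
  expect_identical(lg$significant[lg$symbol == "S" & lg$position == 5],
                   lg2$significant[lg2$symbol == "S" & lg2$position == 5])
})

test_that("logo reports round-trip to TSV and render to a plot", {
  pos <- generateDataset(100, 0, motif = motifSpec(4, "G", 0.9, 0),
                         seed = 71)
  neg <- generateDataset(0, 100, motif = motifSpec(), seed = 73)
  lg <- twoSampleLogo(pos, neg)
  path <- tempfile(fileext = ".tsv")
  writeLogoReport(lg, path)
  back <- read.delim(path)
  expect_identical(nrow(back), 180L)
  expect_equal(back$p, lg$p, tolerance = 1e-6)
  p <- plotTwoSampleLogo(lg)
  expect_s3_class(p, "ggplot")
})
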