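test_that("stratified folds cover the data, are disjoint and balanced", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(30:120, 1)
    y <- sample(c(1, -1), n, replace = TRUE, prob = c(0.6, 0.4))
    if (min(table(y)) < 10) next
    f <- tcreact:::stratifiedFolds(y, 10)
    expect_setequal(sort(unique(f)), 1:10)
    sizes <- tabulate(f, 10)
    expect_lte(max(sizes) - min(sizes), 1L)
    # class proportions per fold within one member of exact stratification
    for (k in 1:10) {
      npos <- sum(y[f == k] == 1)
      expect_lte(abs(npos - sizes[k] * mean(y == 1)), 1.5)
    }
  }
  expect_error(tcreact:::stratifiedFolds(c(1, -1), 5), "degenerate")
})

test_that("nested CV is reproducible from its seed and records bookkeeping", {
  ds <- generateDataset(30, 30, motif = motifSpec(4, "G", 0.7, 0.1),
                        seed = 1)
  g <- gridSpec(C = c(0.5, 1), d = c(5, 9))
  r1 <- nestedCV(ds, g, nRuns = 2, seed = 17, outerFolds = 5,
                 innerFolds = 5)
  r2 <- nestedCV(ds, g, nRuns = 2, seed = 17, outerFolds = 5,
                 innerFolds = 5)
  expect_identical(cvFolds(r1), cvFolds(r2))
  expect_identical(cvSummary(r1), cvSummary(r2))
  f <- cvFolds(r1)
  expect_identical(nrow(f), 10L)            # 2 runs x 5 folds
  expect_true(all(f$C %in% g$C & f$d %in% g$d))
  expect_identical(r1@seed, 17L)
  # different seed gives a different partition
  r3 <- nestedCV(ds, g, nRuns = 2, seed = 18, outerFolds = 5,
                 innerFolds = 5)
  expect_false(identical(cvFolds(r1)$AUC, cvFolds(r3)$AUC))
})

test_that("nested CV recovers a planted rule and stays at chance on null labels", {
  ds <- makeRuleData(n = 120, seed = 3)
  rep1 <- nestedCV(ds, gridSpec(C = 1, d = 9), nRuns = 1, seed = 7)
  expect_gte(mean(cvRuns(rep1)$AUC), 0.95)
  null <- generateDataset(60, 60, motif = motifSpec(), seed = 4)
  rep0 <- nestedCV(null, gridSpec(C = 1, d = 9), nRuns = 3, seed = 8)
  expect_gte(mean(cvRuns(rep0)$AUC), 0.35)
  expect_lte(mean(cvRuns(rep0)$AUC), 0.65)
})

test_that("grid validation and degenerate inputs error out", {
  ds <- makeRuleData(n = 60, seed = 2)
  expect_error(gridSpec(C = numeric(0)), "empty")
  expect_error(gridSpec(C = -1), "C values")
  expect_error(nestedCV(ds, gridSpec(C = 1, d = 12)), "exceed")
  tiny <- makeRuleData(n = 10, seed = 2)
  expect_error(nestedCV(tiny, gridSpec(C = 1, d = 9)), "too small|at least")
})

test_that("learning curve is deterministic, errors on oversize requests, and improves with data", {
  ds <- generateDataset(150, 150,
                        motif = motifSpec(c(4, 6), c("G", "V"),
                                          c(0.7, 0.6), c(0.1, 0.1)),
                        seed = 10)
  lc1 <- learningCurve(ds, sizes = c(30, 150), seed = 20)
  lc2 <- learningCurve(ds, sizes = c(30, 150), seed = 20)
  expect_identical(lc1, lc2)
  expect_identical(lc1$size, c(30, 150))
  expect_error(learningCurve(ds, sizes = 1000, seed = 1), "exceeds")
  # majority over seeds: more data never hurts on motif data
  wins <- 0
  for (s in 21:25) {
    lc <- learningCurve(ds, sizes = c(30, 150), seed = s)
    wins <- wins + (lc$AUC_test[2] >= lc$AUC_test[1])
  }
  expect_gte(wins, 3)
})

test_that("learning curve at the full pool equals a plain train/evaluate run", {
  ds <- makeRuleData(n = 80, seed = 44)
  y <- labels(ds)
  lc <- learningCurve(ds, sizes = NULL, seed = 30)
  expect_identical(lc$size[nrow(lc)], 40L)  # half of 80
  expect_gte(lc$AUC_test[nrow(lc)], 0.9)    # separable rule, full pool
})

test_that("the mean-property RBF baseline learns composition but not position", {
  # labels driven by mean hydrophobicity: baseline succeeds
  set.seed(31)
  peps <- randomPeptides(160)
  kd <- tcreact:::RECODING_SCALES$hydrophobicity$values
  meanH <- vapply(strsplit(peps, ""), function(cs) mean(kd[cs]), numeric(1))
  yH <- ifelse(meanH > stats::median(meanH), 1, -1)
  dsH <- PeptideSet(peps, yH)
  repH <- baselinePropertySVM(dsH, C = 1, gamma = c(0.5, 2), nRuns = 1,
                              seed = 5, outerFolds = 5, innerFolds = 5)
  expect_gte(mean(cvRuns(repH)$AUC), 0.9)
  # composition-matched position-swap data: baseline is blind
  suite <- defaultBenchmarkSuite(seed = 9, nPos = 60, nNeg = 60)
  repP <- baselinePropertySVM(suite$positionSwap, C = 1, gamma = c(0.5, 2),
                              nRuns = 1, seed = 5, outerFolds = 5,
                              innerFolds = 5)
  expect_lte(mean(cvRuns(repP)$AUC), 0.65)
  # while the string kernel is not
  repK <- nestedCV(suite$positionSwap, gridSpec(C = 1, d = 9), nRuns = 1,
                   seed = 5, outerFolds = 5, innerFolds = 5)
  expect_gte(mean(cvRuns(repK)$AUC), 0.9)
})

test_that("CV reports serialize to TSV + JSON", {
  ds <- makeRuleData(n = 60, seed = 13)
  rep <- nestedCV(ds, gridSpec(C = 1, d = 9), nRuns = 1, seed = 2,
                  outerFolds = 5, innerFolds = 5)
  prefix <- tempfile()
  writeCVReport(rep, prefix)
  folds <- read.delim(paste0(prefix, "_folds.tsv"))
  expect_identical(nrow(folds), 5L)
  summ <- jsonlite::fromJSON(paste0(prefix, "_summary.json"))
  expect_identical(summ$seed, 2L)
  expect_setequal(summ$summary$metric, c("ACC", "MCC", "AUC"))
})

test_that("nested-CV estimates agree with a large held-out estimate", {
  # on the planted rule both routes must report the same (near-perfect)
  # discriminability; disagreement would reveal fold leakage or bias
  for (s in 1:5) {
    ds <- makeRuleData(n = 120, seed = 400 + s)
    cvAUC <- mean(cvRuns(nestedCV(ds, gridSpec(C = 1, d = 9), nRuns = 1,
                                  seed = 500 + s))$AUC)
    holdout <- makeRuleData(n = 1000, seed = 600 + s)
    m <- trainModel(ds, kernelSpec(9), C = 1)
    hoAUC <- aucScore(decisionScores(m, holdout), labels(holdout))
    expect_lt(abs(cvAUC - hoAUC), 0.05)
  }
})

test_that("across-run spread is small relative to the mean", {
  ds <- generateDataset(60, 60, motif = motifSpec(4, "G", 0.7, 0.1),
                        seed = 700)
  rep <- nestedCV(ds, gridSpec(C = 1, d = 9), nRuns = 4, seed = 701)
  s <- cvSummary(rep)
  expect_lt(s$sd[s$metric == "AUC"], 0.05)
})
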