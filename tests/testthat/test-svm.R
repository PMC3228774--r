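test_that("two-point training recovers the closed-form dual solution", {
  ps <- PeptideSet(c("LLFGYPVYV", "GILGFVFTL"), c(1, -1))
  m <- trainModel(ps, kernelSpec(9), C = 1)
  K <- gramMatrix(ps)
  # symmetric 2-point problem: alpha1 = alpha2 = min(C, 2/(K11+K22-2K12)),
  # bias 0, antisymmetric scores
  aStar <- min(1, 2 / (K[1, 1] + K[2, 2] - 2 * K[1, 2]))
  expect_equal(unname(dualAlpha(m)), rep(aStar, 2), tolerance = 1e-6)
  pr <- predict(m, ps)
  expect_gt(pr$score[1], 0)
  expect_lt(pr$score[2], 0)
  expect_equal(pr$score[1] + pr$score[2], 0, tolerance = 1e-6)
  expect_equal(pr$label, c(1L, -1L))
})

test_that("dual feasibility and KKT hold after every fit", {
  set.seed(21)
  for (C in c(0.1, 1, 10)) {
    ds <- PeptideSet(randomPeptides(40), sample(c(1, -1), 40, TRUE,
                                                prob = c(0.5, 0.5)))
    m <- trainModel(ds, kernelSpec(6), C = C)
    a <- dualAlpha(m)
    y <- labels(ds)
    expect_true(all(a >= -1e-9 & a <= C + 1e-9))
    expect_lt(abs(sum(a * y)), 1e-6)
    # stationarity via the margins: free SVs sit on the margin
    sc <- predict(m, ds)$score
    free <- a > 1e-6 & a < C - 1e-6
    if (any(free))
      expect_lt(max(abs(y[free] * sc[free] - 1)), 1e-5)
  }
})

test_that("solver dual objective matches a brute-force oracle on small problems", {
  set.seed(33)
  for (rep in 1:4) {
    n <- 10
    ds <- PeptideSet(randomPeptides(n), rep(c(1, -1), n / 2))
    K <- gramMatrix(ds, kernelSpec(9))
    m <- trainModel(ds, kernelSpec(9), C = 1)
    aoracle <- dualOracle(K, labels(ds), 1, iters = 60000)
    objMine <- dualObjectiveOf(dualAlpha(m), K, labels(ds))
    objOracle <- dualObjectiveOf(aoracle, K, labels(ds))
    expect_equal(dualObjective(m), objMine, tolerance = 1e-8)
    expect_lt(abs(objMine - objOracle), 1e-4)
    expect_lte(objMine, objOracle + 1e-6)  # the solver is never worse
  }
})

test_that("solver is at least as optimal as an independent SVM library", {
  skip_if_not_installed("kernlab")
  set.seed(55)
  ds <- PeptideSet(randomPeptides(60), sample(rep(c(1, -1), 30)))
  K <- gramMatrix(ds, kernelSpec(9))
  y <- labels(ds)
  m <- trainModel(ds, kernelSpec(9), C = 1)
  km <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                      factor(y, levels = c(1, -1)), kernel = "matrix",
                      C = 1, type = "C-svc", scaled = FALSE)
  ak <- numeric(60)
  ak[unlist(kernlab::alphaindex(km))] <- abs(unlist(kernlab::coef(km)))
  expect_lte(dualObjectiveOf(dualAlpha(m), K, y),
             dualObjectiveOf(ak, K, y) + 1e-6)
})

test_that("scores are invariant to training-set permutation and antisymmetric under label flips", {
  set.seed(8)
  ds <- makeRuleData(n = 80, seed = 12)
  # make it inseparable so the fit is non-trivial
  y <- labels(ds)
  y[1:6] <- -y[1:6]
  ds <- PeptideSet(as.character(ds), y)
  m1 <- trainModel(ds, kernelSpec(9), C = 1)
  perm <- sample(length(ds))
  m2 <- trainModel(ds[perm], kernelSpec(9), C = 1)
  q <- randomPeptides(15)
  expect_lt(max(abs(decisionScores(m1, q) - decisionScores(m2, q))), 1e-6)
  m3 <- trainModel(PeptideSet(as.character(ds), -y), kernelSpec(9), C = 1)
  expect_lt(max(abs(decisionScores(m1, q) + decisionScores(m3, q))), 1e-6)
})

test_that("a planted single-position rule is fit almost perfectly", {
  ds <- makeRuleData(n = 100, seed = 77)
  m <- trainModel(ds, kernelSpec(9), C = 1)
  pr <- predict(m, ds)
  expect_gte(mean(pr$label == labels(ds)), 0.99)
  # held-out generalization from the same rule
  holdout <- makeRuleData(n = 200, seed = 78)
  m2 <- trainModel(makeRuleData(n = 200, seed = 79), kernelSpec(9), C = 1)
  prh <- predict(m2, holdout)
  expect_gte(mean(prh$label == labels(holdout)), 0.95)
})

test_that("prediction applies the strict zero threshold and validates input", {
  ds <- PeptideSet(c("LLFGYPVYV", "GILGFVFTL"), c(1, -1))
  m <- trainModel(ds, kernelSpec(9), C = 1)
  # exact zero maps to non-immunogenic
  fake <- m
  fake@coefficients[] <- 0
  fake@bias <- 0
  pr0 <- predict(fake, "AAAAAAAAA")
  expect_identical(pr0$score, 0)
  expect_identical(pr0$label, -1L)
  expect_identical(pr0$call, "non-immunogenic")
  expect_error(predict(m, "LLFG"), "length")
  expect_error(predict(m, "LLFGYPVYX"), "non-canonical")
  expect_error(trainModel(PeptideSet(randomPeptides(5), rep(1, 5))),
               "both classes")
  expect_error(trainModel(ds, C = -1), "C must be")
})

test_that("the final-model wrapper is exactly train(C = 1, d = 9) and deterministic", {
  ds <- makeRuleData(n = 60, seed = 5)
  m1 <- trainFinalModel(ds)
  m2 <- trainModel(ds, kernelSpec(9), C = 1)
  q <- randomPeptides(10)
  expect_identical(decisionScores(m1, q), decisionScores(m2, q))
  m3 <- trainFinalModel(ds)
  expect_identical(decisionScores(m1, q), decisionScores(m3, q))
  expect_identical(modelCost(m1), 1)
  expect_identical(kernelDegree(modelKernel(m1)), 9L)
})

test_that("model serialization round-trips with bit-identical scores", {
  ds <- makeRuleData(n = 60, seed = 31)
  m <- trainModel(ds, kernelSpec(7), C = 0.5)
  path <- tempfile(fileext = ".json")
  writeModel(m, path)
  m2 <- readModel(path)
  q <- randomPeptides(25)
  expect_identical(decisionScores(m, q), decisionScores(m2, q))
  expect_identical(supportCoefficients(m), supportCoefficients(m2))
  expect_identical(modelBias(m), modelBias(m2))
  expect_identical(kernelDegree(modelKernel(m2)), 7L)
  bad <- tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', bad)
  expect_error(readModel(bad), "model archive")
})

test_that("raising C tends to reduce margin violations on inseparable data", {
  # soft-margin trade-off: a higher error penalty cannot systematically
  # produce more violations; checked as a majority trend over seeds
  wins <- 0
  for (s in 1:5) {
    ds <- generateDataset(40, 40, motif = motifSpec(4, "G", 0.7, 0.2),
                          seed = 800 + s)
    nViol <- vapply(c(0.1, 10), function(C) {
      m <- trainModel(ds, kernelSpec(9), C = C)
      sum(labels(ds) * predict(m, ds)$score < 1 - 1e-6)
    }, numeric(1))
    wins <- wins + (nViol[2] <= nViol[1])
  }
  expect_gte(wins, 3)
})
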