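test_that("capture histories are tabulated correctly", {
  m <- dmFromSets(list(e1 = "u1", e2 = "x", e3 = "u1"))
  h <- captureHistories(m)
  expect_identical(h@t, 3L)
  expect_identical(unname(h@frequencies[["101"]]), 1L)
  expect_identical(h@n, 2L)

  # A = {u1,u2}, B = {u2,u3}: 10 -> 1, 01 -> 1, 11 -> 1
  h2 <- captureHistories(dmFromSets(list(A = c("u1", "u2"),
                                         B = c("u2", "u3"))))
  expect_identical(unname(h2@frequencies[c("10", "01", "11")]),
                   c(1L, 1L, 1L))
  expect_identical(h2@n, 3L)
})

test_that("the cap keeps the largest experiments in chronological order", {
  sets <- lapply(setNames(3:8, paste0("e", 1:6)),
                 function(n) sprintf("u%02d", seq_len(n)))
  m <- dmFromSets(sets)
  h <- captureHistories(m, cap = 4L)
  expect_identical(h@experimentIds, paste0("e", 3:6))  # 4 largest, in order
  expect_error(captureHistories(m, cap = 21L), "unmanageable")
})

test_that("two-occasion Mt reduces to the Petersen closed form", {
  sets <- list(A = sprintf("u%03d", 1:100), B = sprintf("u%03d", 76:125))
  est <- fitLoglinear(captureHistories(dmFromSets(sets)), "Mt")
  expect_equal(nHat(est), 200, tolerance = 1e-8)
  pet <- petersenTwoList(sets$A, sets$B)
  expect_equal(nHat(pet), 200)

  # property: random two-list instances
  set.seed(77)
  for (i in 1:25) {
    n10 <- sample(5:400, 1); n01 <- sample(5:400, 1); n11 <- sample(5:400, 1)
    u <- sprintf("u%04d", seq_len(n10 + n01 + n11))
    A <- u[seq_len(n10 + n11)]
    B <- u[(n10 + 1):(n10 + n11 + n01)]
    mt <- nHat(fitLoglinear(captureHistories(dmFromSets(list(A = A, B = B))),
                            "Mt"))
    expect_equal(mt, nHat(petersenTwoList(A, B)), tolerance = 1e-6)
  }
})

test_that("Petersen handles nesting, disjoint lists and Chapman correction", {
  A <- sprintf("u%03d", 1:80)
  expect_equal(nHat(petersenTwoList(A, A[1:20])), 80)  # subset: m = n2
  expect_error(petersenTwoList(A, "zzz"), "disjoint")
  p <- petersenTwoList(sprintf("u%03d", 1:100), sprintf("u%03d", 76:125))
  expect_equal(p@details$chapman, 101 * 51 / 26 - 1)
  expect_gt(p@se, 0)
})

test_that("Chao Mh matches its closed-form lower bound without temporal effects", {
  sim <- simulateDetectionMatrix(500, 5, occasionSd = 0, seed = 11)
  h <- captureHistories(sim$matrix, cap = 5L)
  est <- fitLoglinear(h, "MhChao")
  fs <- captureCountFreqs(h)
  closedForm <- h@n + (4 / 5) * fs[["1"]]^2 / (2 * fs[["2"]])
  expect_equal(nHat(est), closedForm, tolerance = 1e-6)
})

test_that("glm fits agree with direct likelihood maximization", {
  sim <- simulateDetectionMatrix(500, 5, seed = 19)
  h <- captureHistories(sim$matrix, cap = 5L)
  for (mod in c("M0", "Mt", "MthChao")) {
    est <- fitLoglinear(h, mod)
    # the constrained (drop-and-refit) solution equals the unconstrained
    # optimum of the reduced design: give the oracle the same design
    oracle <- directLoglinearNhat(h, mod, dropEta = est@details$droppedEta)
    expect_equal(nHat(est), oracle$nHat, tolerance = 1e-3)
    expect_equal(est@details$logLik, oracle$logLik, tolerance = 1e-4)
    # AIC bookkeeping: -2 loglik + 2 npar
    expect_equal(est@aic,
                 -2 * est@details$logLik + 2 * est@details$nParameters,
                 tolerance = 1e-8)
    # IRLS improved on the constant-fit start
    expect_lte(est@details$deviance, est@details$nullDeviance + 1e-9)
  }
})

test_that("nothing-unseen data give nHat close to n", {
  m <- DetectionMatrix(matrix(1L, 40, 4,
                              dimnames = list(sprintf("u%02d", 1:40),
                                              paste0("e", 1:4))),
                       unitLevel = "protein")
  # boundary case: the unseen-mass cell is estimated at numerically zero
  est <- suppressWarnings(fitLoglinear(captureHistories(m), "Mt"))
  expect_equal(nHat(est), 40, tolerance = 1e-3)
})

test_that("nHat is never below the observed count", {
  set.seed(23)
  for (s in 1:5) {
    sim <- simulateDetectionMatrix(300, 5, seed = 700 + s)
    h <- captureHistories(sim$matrix, cap = 5L)
    for (mod in c("M0", "Mt", "MhChao", "MthChao"))
      expect_gte(nHat(fitLoglinear(h, mod)), h@n)
  }
})

test_that("AIC selection prefers simple models on homogeneous data and Mth under heterogeneity", {
  # homogeneous catchability, no temporal effects: not MthChao
  simH <- simulateDetectionMatrix(2000, 5, catchShape1 = 60,
                                  catchShape2 = 140, occasionSd = 0,
                                  seed = 41)
  selH <- selectModel(captureHistories(simH$matrix, cap = 5L))
  expect_true(modelName(selH) %in% c("M0", "Mt"))

  # strong heterogeneity + temporal effects: the Chao models win
  simT <- simulateDetectionMatrix(2000, 6, catchShape1 = 0.4,
                                  catchShape2 = 1.2, occasionSd = 0.6,
                                  seed = 43)
  selT <- selectModel(captureHistories(simT$matrix, cap = 6L))
  expect_true(modelName(selT) %in% c("MhChao", "MthChao"))

  # the selected AIC is the minimum over the fitted models
  aics <- vapply(selT@details$allFits, function(f) f@aic, numeric(1))
  expect_equal(selT@aic, min(aics))

  # minimal smoke table: all frequencies 1 at t = 3
  h <- new("CaptureHistoryTable", t = 3L,
           frequencies = rep(1L, 7), n = 7L,
           experimentIds = c("a", "b", "c"))
  expect_true(is.finite(nHat(selectModel(h))))
})

test_that("jackknife is reproducible, seed-stream based, and degenerate-safe", {
  sim <- simulateDetectionMatrix(400, 8, seed = 55)
  m <- sim$matrix
  j1 <- jackknifeAbundance(m, eligibilityThreshold = 1L, subsetSize = 5L,
                           nReps = 8L, seed = 99L)
  j2 <- jackknifeAbundance(m, eligibilityThreshold = 1L, subsetSize = 5L,
                           nReps = 8L, seed = 99L)
  expect_identical(j1@replicates, j2@replicates)
  expect_equal(j1@cv, j1@sd / j1@mean)

  # exactly subsetSize eligible experiments: no sampling variability
  j3 <- jackknifeAbundance(m, eligibilityThreshold = 1L, subsetSize = 8L,
                           nReps = 5L, seed = 1L)
  expect_equal(j3@sd, 0)

  expect_warning(
    jackknifeAbundance(m, eligibilityThreshold = 1L, subsetSize = 5L,
                       nReps = 1L, seed = 1L),
    "single replicate")
  expect_error(
    jackknifeAbundance(m, eligibilityThreshold = 10000L, subsetSize = 5L,
                       nReps = 2L, seed = 1L),
    "threshold")
})

test_that("jackknife mean brackets the truth on a synthetic population", {
  sim <- simulateDetectionMatrix(600, 12, catchShape1 = 3, catchShape2 = 3,
                                 seed = 61)
  j <- jackknifeAbundance(sim$matrix, eligibilityThreshold = 50L,
                          subsetSize = 8L, nReps = 12L, seed = 5L)
  expect_lt(abs(j@mean - 600), max(2 * j@sd, 0.15 * 600))
})
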