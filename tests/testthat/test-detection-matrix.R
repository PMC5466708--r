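test_that("CSV read preserves structure, totals and column order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,111,222",
               "P1_S10,1,0",
               "P1_T20,1,1",
               "P2_S5,,1"), path)          # empty cell = 0
  m <- readDetectionMatrix(path, unitLevel = "site")
  expect_identical(unitIds(m), c("P1_S10", "P1_T20", "P2_S5"))
  expect_identical(experimentIds(m), c("111", "222"))
  expect_identical(unname(colSums(detections(m))), c(2, 2))
  expect_identical(nrow(m), 3L)
})

test_that("malformed cells, duplicate ids and all-zero rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("unit_id,e1,e2", "u1,1,2", "u2,1,0"), path)
  expect_error(readDetectionMatrix(path, "protein"), "non-binary.*u1")

  writeLines(c("unit_id,e1,e2", "u1,1,0", "u1,0,1"), path)
  expect_error(readDetectionMatrix(path, "protein"), "duplicate unit")

  writeLines(c("unit_id,e1,e1", "u1,1,0", "u2,0,1"), path)
  expect_error(readDetectionMatrix(path, "protein"), "duplicate experiment")

  mat <- matrix(c(1L, 0L, 0L, 0L), 2,
                dimnames = list(c("u1", "u2"), c("e1", "e2")))
  expect_error(DetectionMatrix(mat, "protein"), "no detections.*u2")
})

test_that("write/read round trip is the identity", {
  sim <- simulateDetectionMatrix(80, 4, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDetectionMatrix(sim$matrix, path)
  back <- readDetectionMatrix(path, unitLevel = "site")
  expect_identical(detections(back), detections(sim$matrix))
  expect_identical(unitLevel(back), unitLevel(sim$matrix))
})

test_that("collapseToProteins applies the union rule over sites", {
  m <- dmFromSets(list(e1 = c("P1_S10", "P2_S5"), e2 = "P1_T20"),
                  unitLevel = "site")
  p <- collapseToProteins(m)
  expect_identical(unitLevel(p), "protein")
  expect_identical(sort(unitIds(p)), c("P1", "P2"))
  expect_identical(unname(detections(p)["P1", ]), c(1L, 1L))
  expect_identical(unname(detections(p)["P2", ]), c(1L, 0L))
  expect_lte(nrow(p), nrow(m))

  # one site per protein: identical up to renaming
  m1 <- dmFromSets(list(e1 = c("A_S1", "B_T2"), e2 = "B_T2"),
                   unitLevel = "site")
  p1 <- collapseToProteins(m1)
  expect_identical(unname(detections(p1)), unname(detections(m1)))

  expect_error(collapseToProteins(
    dmFromSets(list(e1 = "oddid"), unitLevel = "site")),
    "parsable protein prefix")
})

test_that("collapse and merge commute", {
  sim <- simulateDetectionMatrix(150, 5, sitesPerProtein = 3, seed = 21)
  a <- mergeExperiments(collapseToProteins(sim$matrix), "m")
  b <- collapseToProteins(mergeExperiments(sim$matrix, "m"))
  expect_identical(detections(a)[sort(unitIds(a)), , drop = FALSE],
                   detections(b)[sort(unitIds(b)), , drop = FALSE])
})

test_that("filterMinExperiments keeps exactly the rows with sum >= k and is monotone", {
  m <- dmFromSets(list(e1 = c("a", "b", "c"), e2 = c("a", "b"),
                       e3 = c("a", "d")))
  expect_identical(unitIds(filterMinExperiments(m, 3)), "a")
  expect_identical(sort(unitIds(filterMinExperiments(m, 2))), c("a", "b"))
  expect_identical(detections(filterMinExperiments(m, 1)), detections(m))
  for (k in 1:3)
    expect_true(all(unitIds(filterMinExperiments(m, k + 1)) %in%
                      unitIds(filterMinExperiments(m, k))))
})

test_that("mergeExperiments yields the non-redundant union", {
  m <- dmFromSets(list(e1 = c("a", "b"), e2 = c("b", "c"), e3 = "c"))
  mg <- mergeExperiments(m, "all")
  expect_identical(ncol(mg), 1L)
  expect_identical(unname(sum(detections(mg))), 3L)   # union size
  expect_identical(nrow(mg), nrow(m))
  # curve consistency: final y of the saturation curve equals the union
  expect_identical(sum(detections(mg)),
                   as.integer(max(curvePoints(buildCurve(m))$y)))
})

test_that("jaccardQC computes the intersection-over-union similarity", {
  m <- dmFromSets(list(A = letters[1:5], B = letters[1:5],
                       C = letters[6:10]))
  js <- jaccardQC(m)
  expect_equal(js@similarity["A", "B"], 1)
  expect_equal(js@similarity["A", "C"], 0)
  expect_true(isSymmetric(js@similarity))
  expect_equal(unname(diag(js@similarity)), rep(1, 3))

  # |A∩B| = 2, |A∪B| = 8 -> 0.25
  m2 <- dmFromSets(list(A = letters[1:5], B = letters[4:8]))
  expect_equal(jaccardQC(m2)@similarity["A", "B"], 0.25)
  expect_true(js@meanSimilarity <= js@maxSimilarity)
})

test_that("jaccardQC is invariant to row permutation", {
  sim <- simulateDetectionMatrix(100, 4, seed = 3)
  m <- sim$matrix
  set.seed(9)
  perm <- sample(nrow(m))
  mp <- DetectionMatrix(detections(m)[perm, ], unitLevel(m))
  expect_equal(jaccardQC(mp)@similarity, jaccardQC(m)@similarity)
})
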