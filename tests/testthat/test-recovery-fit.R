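syntheticCurve <- function(a, b, cc = 0, xs = seq(1000, 20000, by = 1000)) {
  new("SaturationCurve",
      points = data.frame(x = c(0, xs),
                          y = c(0, a * (1 - exp(-xs / b)) + cc * xs)),
      orderingLabel = "chronological", experimentIds = character())
}

test_that("noiseless generating parameters are recovered exactly", {
  fit <- fitRecovery(syntheticCurve(1000, 5000))
  expect_equal(fit@a, 1000, tolerance = 1e-6)
  expect_equal(fit@b, 5000, tolerance = 1e-6)
  expect_lt(fit@sse, 1e-6)
  expect_true(fit@converged)
})

test_that("free noise slope is recovered and matches the grid-search optimum", {
  cv <- syntheticCurve(1000, 5000, cc = 0.01)
  fit <- fitRecovery(cv, noiseTerm = TRUE)
  # independent brute-force oracle over (a, b, c)
  grid <- gridSearchSSE(curvePoints(cv),
                        aGrid = seq(900, 1100, by = 10),
                        bGrid = seq(4000, 6000, by = 100),
                        cGrid = seq(0, 0.02, by = 0.001))
  expect_equal(grid$a, 1000)
  expect_equal(grid$c, 0.01)
  expect_equal(fit@a, 1000, tolerance = 1e-3)
  expect_equal(fit@c, 0.01, tolerance = 1e-4)
  expect_lte(fit@sse, grid$sse + 1e-8)
})

test_that("optimizer SSE is near the dense-grid optimum on short noisy curves", {
  set.seed(42)
  for (rep in 1:3) {
    xs <- sort(runif(7, 500, 12000))
    ys <- cummax(800 * (1 - exp(-xs / 3000)) + rnorm(7, 0, 15))
    ys <- pmin(ys, xs)
    pts <- data.frame(x = c(0, xs), y = c(0, ys))
    cv <- new("SaturationCurve", points = pts,
              orderingLabel = "custom", experimentIds = character())
    fit <- fitRecovery(cv)
    grid <- gridSearchSSE(pts,
                          aGrid = seq(max(ys), 3 * max(ys), length.out = 120),
                          bGrid = seq(200, 3 * max(xs), length.out = 120))
    expect_lte(fit@sse, grid$sse * 1.01)
  }
})

test_that("fixed-c fitting holds the slope and reports it as fixed", {
  cv <- syntheticCurve(1000, 5000, cc = 0.01)
  fit <- fitRecovery(cv, noiseTerm = TRUE, fixedC = 0.01)
  expect_identical(fit@c, 0.01)
  expect_true(fit@cFixed)
  expect_equal(fit@a, 1000, tolerance = 1e-5)
})

test_that("insufficient points raise an error", {
  short <- new("SaturationCurve",
               points = data.frame(x = c(0, 10, 20), y = c(0, 8, 14)),
               orderingLabel = "custom", experimentIds = character())
  expect_error(fitRecovery(short), "insufficient saturation data")
})

test_that("predict obeys the model identities", {
  fit <- fitRecovery(syntheticCurve(1000, 5000))
  expect_identical(predict(fit, 0), 0)
  # 63.2% point: y(b) = a (1 - 1/e)
  expect_equal(predict(fit, fit@b) / fit@a, 1 - exp(-1), tolerance = 1e-9)
  # a = 1000, b = 5000, x = 5000 -> 632 rounded
  expect_equal(round(predict(fit, 5000)), 632)
  # strictly increasing, concave, below the asymptote
  xs <- seq(0, 1e5, length.out = 200)
  ys <- predict(fit, xs)
  expect_true(all(diff(ys) > 0))
  expect_true(all(diff(diff(ys)) < 1e-9))
  expect_true(all(ys < fit@a))
  # with a positive noise slope: still strictly increasing
  fitn <- fitRecovery(syntheticCurve(1000, 5000, 0.01), noiseTerm = TRUE)
  expect_true(all(diff(predict(fitn, xs)) > 0))
})

test_that("parameter recovery on simulated accumulation data at high saturation", {
  avals <- vapply(1:5, function(s) {
    sim <- simulateDetectionMatrix(800, 20, seed = 600 + s)
    sat <- nrow(sim$matrix) / 800
    expect_gt(sat, 0.8)
    fitRecovery(buildCurve(sim$matrix))@a
  }, numeric(1))
  expect_lt(abs(mean(avals) - 800) / 800, 0.1)
})

test_that("half-series fitting stays within a bounded factor of the full fit", {
  sim <- simulateDetectionMatrix(800, 20, seed = 31)
  m <- sim$matrix
  full <- fitRecovery(buildCurve(m))@a
  halfOrder <- perturbOrder(m, "half_experiments")
  half <- fitRecovery(buildCurve(m, halfOrder,
                                 orderingLabel = "half_experiments"))@a
  expect_lt(abs(half - full) / full, 0.2)
})
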