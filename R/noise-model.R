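## False-positive model: noise is stochastic, drawn from a large pool, and
## low within each experiment -- so fake units barely overlap between
## experiments and inflate any overlap-based abundance estimate.

NOISE_PREFIX <- "NOISE_"

#' Inject stochastic false-positive detections
#'
#' For each experiment with `d` detections, adds `round(rate * d)` fake
#' detections (round half-to-even, base R `round`), drawn uniformly without
#' replacement from a shared pool of `poolMultiplier * nrow(x)` fake unit
#' ids.  Because the pool is shared, the same fake unit can in principle
#' recur in two experiments, but with a large pool the expected overlap is
#' hypergeometric and tiny — mirroring the behaviour assumed of real
#' false positives.  Fake ids carry the reserved prefix `"NOISE_"`; real
#' detections are never touched, so stripping prefixed rows restores the
#' input exactly.
#'
#' @param x a [DetectionMatrix-class].
#' @param rate per-experiment false-positive rate, in (0, 1).
#' @param poolMultiplier pool size as a multiple of the real unit count
#'   (default 10).
#' @param seed integer seed.
#' @return a [DetectionMatrix-class] with fake rows appended.
#' @export
injectNoise <- function(x, rate, poolMultiplier = 10, seed) {
  stopifnot(is(x, "DetectionMatrix"), rate > 0, rate < 1)
  if (any(startsWith(unitIds(x), NOISE_PREFIX)))
    stop("input already contains ", NOISE_PREFIX, "-prefixed units")
  poolSize <- ceiling(poolMultiplier * nrow(x))
  d <- colSums(detections(x))
  nAdd <- round(rate * d)
  if (any(nAdd > poolSize))
    stop("fake-unit pool (", poolSize, ") smaller than required draws; ",
         "increase poolMultiplier")
  if (all(nAdd == 0L)) return(x)
  pool <- sprintf("%s%06d", NOISE_PREFIX, seq_len(poolSize))
  set.seed(as.integer(seed))
  fake <- matrix(0L, nrow = poolSize, ncol = ncol(x),
                 dimnames = list(pool, experimentIds(x)))
  for (j in seq_len(ncol(x))) {
    if (nAdd[j] > 0L)
      fake[sample.int(poolSize, nAdd[j]), j] <- 1L
  }
  fake <- fake[rowSums(fake) > 0L, , drop = FALSE]
  DetectionMatrix(rbind(detections(x), fake), unitLevel = unitLevel(x))
}

#' Strip injected fake units from a matrix
#'
#' @param x a [DetectionMatrix-class] possibly containing `"NOISE_"` rows.
#' @return the matrix restricted to real units.
#' @export
stripNoise <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  keep <- !startsWith(unitIds(x), NOISE_PREFIX)
  DetectionMatrix(detections(x)[keep, , drop = FALSE],
                  unitLevel = unitLevel(x))
}

#' Noise-adjust an abundance estimate by injection
#'
#' Estimates how much a given level of false-positive contamination
#' inflates an abundance estimate, and corrects downwards by that amount:
#' noise at rate k is injected `nInjections` times, the estimator re-run on
#' each contaminated matrix, and the mean inflation
#' `delta = mean(inflated) - original` subtracted from the original
#' estimate.  The correction extrapolates linearly: injecting k% extra
#' noise is assumed to inflate the estimate by the same amount as the k%
#' noise already present in the data.
#'
#' @param x a [DetectionMatrix-class].
#' @param estimator a function `DetectionMatrix -> numeric(1)` returning an
#'   abundance estimate, e.g.
#'   `function(m) nHat(fitLoglinear(captureHistories(m), "MthChao"))`.
#' @param rate contamination level, e.g. 0.01, 0.05, 0.10.
#' @param nInjections independent injection replicates (default 10).
#' @param poolMultiplier passed to [injectNoise()].
#' @param seed master seed; each replicate uses a derived stream.
#' @return a [NoiseAdjustment-class].
#' @export
adjustForNoise <- function(x, estimator, rate, nInjections = 10L,
                           poolMultiplier = 10, seed) {
  stopifnot(is(x, "DetectionMatrix"), is.function(estimator))
  original <- estimator(x)
  set.seed(as.integer(seed))
  repSeeds <- sample.int(.Machine$integer.max, nInjections)
  inflated <- vapply(seq_len(nInjections), function(r) {
    tryCatch({
      xi <- injectNoise(x, rate, poolMultiplier = poolMultiplier,
                        seed = repSeeds[r])
      estimator(xi)
    }, error = function(e) {
      warning("injection replicate ", r, " dropped: ",
              conditionMessage(e))
      NA_real_
    })
  }, numeric(1L))
  inflated <- inflated[!is.na(inflated)]
  if (!length(inflated))
    stop("all injection replicates failed")
  delta <- mean(inflated) - original
  new("NoiseAdjustment", noiseRate = rate, originalEstimate = original,
      inflatedEstimates = inflated, delta = delta,
      adjustedEstimate = original - delta,
      nInjections = length(inflated), seed = as.integer(seed))
}

setMethod("show", "NoiseAdjustment", function(object) {
  cat(sprintf("NoiseAdjustment at rate %.2f (%d injections)\n",
              object@noiseRate, object@nInjections))
  cat(sprintf("  original N-hat = %.1f, mean inflated = %.1f\n",
              object@originalEstimate,
              mean(object@inflatedEstimates)))
  cat(sprintf("  delta = %.1f -> adjusted = %.1f\n",
              object@delta, object@adjustedEstimate))
})
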