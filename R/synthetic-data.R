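## Synthetic detection matrices with known ground truth.  The generator
## embodies the assumptions behind the closed-population Mth model: a fixed
## population of N units, each with its own catchability (some
## phosphorylated most of the time, others transiently), per-experiment
## (temporal) detection-rate effects, independent detections given the
## unit-occasion probability, and optional false-positive noise drawn from
## a large pool.

#' Simulate a detection matrix from a closed heterogeneous population
#'
#' Each of `nUnits` true units gets a base catchability drawn from
#' `Beta(catchShape1, catchShape2)` (default Beta(1.2, 3): right-skewed, a
#' few easily-detected units and a long tail of transient ones).  Each
#' experiment gets a log-normal multiplier (sdlog `occasionSd`) modelling
#' temporal effects; the unit-occasion probability is the product, clamped
#' to \\[0, 1\\] (clamp events are counted in the ground truth).
#' Detections are independent Bernoulli draws.  Units never detected are
#' absent from the returned matrix but present in the ground truth.
#' Optional false positives are injected through [injectNoise()] with a
#' seed derived from the same master seed.
#'
#' Unit ids follow the site convention `P<protein>_<residue><position>`;
#' with `sitesPerProtein > 1` consecutive sites share a protein (site
#' counts per protein are `1 + Poisson(sitesPerProtein - 1)`), so the
#' site-to-protein collapse is exercisable on simulated data.
#'
#' @param nUnits true population size N.
#' @param nExperiments number of experiments t.
#' @param catchShape1,catchShape2 Beta shape parameters of the per-unit
#'   catchability distribution.
#' @param occasionSd sdlog of the log-normal per-experiment multiplier
#'   (0 disables temporal effects).
#' @param sitesPerProtein mean number of sites per protein (>= 1).
#' @param noiseRate per-experiment false-positive rate (0 disables noise).
#' @param poolMultiplier fake-unit pool size multiplier for the noise.
#' @param seed integer seed; identical arguments + seed give bit-identical
#'   output.
#' @return a list with `matrix` (a [DetectionMatrix-class]) and
#'   `groundTruth` (list: `N`, `catchability`, `occasionEffects`,
#'   `unitIds` for all N true units, `nClamped`, `seed`).
#' @examples
#' sim <- simulateDetectionMatrix(200, 5, seed = 1)
#' sim$matrix
#' @export
simulateDetectionMatrix <- function(nUnits, nExperiments,
                                    catchShape1 = 1.2, catchShape2 = 3,
                                    occasionSd = 0.4,
                                    sitesPerProtein = 1,
                                    noiseRate = 0, poolMultiplier = 10,
                                    seed) {
  stopifnot(nUnits >= 1, nExperiments >= 1, sitesPerProtein >= 1)
  set.seed(as.integer(seed))
  p <- rbeta(nUnits, catchShape1, catchShape2)
  q <- if (occasionSd > 0) rlnorm(nExperiments, 0, occasionSd)
       else rep(1, nExperiments)
  P <- outer(p, q)
  nClamped <- sum(P > 1)
  P <- pmin(P, 1)
  det <- matrix(rbinom(length(P), 1L, P), nrow = nUnits)

  # site-style ids, grouping consecutive sites into proteins
  if (sitesPerProtein > 1) {
    sizes <- integer()
    while (sum(sizes) < nUnits)
      sizes <- c(sizes, 1L + stats::rpois(nUnits, sitesPerProtein - 1))
    sizes <- sizes[cumsum(sizes) - sizes < nUnits]
    protein <- rep(seq_along(sizes), sizes)[seq_len(nUnits)]
  } else {
    protein <- seq_len(nUnits)
  }
  siteIdx <- stats::ave(protein, protein, FUN = seq_along)
  residue <- sample(c("S", "T", "Y"), nUnits, replace = TRUE,
                    prob = c(0.8, 0.15, 0.05))
  ids <- sprintf("P%05d_%s%d", protein, residue, siteIdx * 7L)
  dimnames(det) <- list(ids, sprintf("EXP%03d", seq_len(nExperiments)))

  observed <- rowSums(det) > 0L
  if (sum(observed) < 2L)
    stop("degenerate configuration: fewer than 2 units observed")
  dm <- DetectionMatrix(det[observed, , drop = FALSE], unitLevel = "site")
  if (noiseRate > 0) {
    noiseSeed <- sample.int(.Machine$integer.max, 1L)
    dm <- injectNoise(dm, noiseRate, poolMultiplier = poolMultiplier,
                      seed = noiseSeed)
  }
  list(matrix = dm,
       groundTruth = list(N = nUnits, catchability = p,
                          occasionEffects = q, unitIds = ids,
                          nClamped = nClamped, seed = as.integer(seed)))
}

#' Simulate paired HTP and LTP compendia over one population
#'
#' Two merged single-column detection matrices over the same closed
#' population, with regime-specific detection probabilities `pHtp` and
#' `pLtp` — the structure assumed by the two-list Petersen analysis.  When
#' the regimes are independent (`correlation = 0`) Petersen is unbiased
#' for N; a positive `correlation` makes a fraction of units detectable by
#' the LTP regime only if the HTP regime also caught them, and at
#' `correlation = 1` the LTP list is a subset of the HTP list, in which
#' case Petersen collapses to the HTP list size and underestimates N.
#'
#' @param nUnits true population size N.
#' @param pHtp,pLtp detection probabilities of the two regimes.
#' @param correlation in \\[0, 1\\]; fraction of units whose LTP detection
#'   requires HTP detection.
#' @param seed integer seed.
#' @return list with `htp`, `ltp` (single-column
#'   [DetectionMatrix-class]es) and `groundTruth`.
#' @export
simulateHtpLtp <- function(nUnits, pHtp, pLtp, correlation = 0, seed) {
  stopifnot(nUnits >= 1, pHtp > 0, pHtp <= 1, pLtp > 0, pLtp <= 1,
            correlation >= 0, correlation <= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("U%06d", seq_len(nUnits))
  htp <- rbinom(nUnits, 1L, pHtp)
  base <- rbinom(nUnits, 1L, pLtp)
  tied <- rbinom(nUnits, 1L, correlation) == 1L
  ltp <- ifelse(tied, htp * base, base)
  mk <- function(v, label) {
    keep <- v == 1L
    DetectionMatrix(matrix(1L, nrow = sum(keep),
                           dimnames = list(ids[keep], label)),
                    unitLevel = "protein")
  }
  if (sum(htp) < 1L || sum(ltp) < 1L)
    stop("degenerate configuration: an empty regime")
  list(htp = mk(htp, "HTP"), ltp = mk(ltp, "LTP"),
       groundTruth = list(N = nUnits, pHtp = pHtp, pLtp = pLtp,
                          correlation = correlation,
                          seed = as.integer(seed)))
}

#' Randomly downsample each experiment's detections
#'
#' Keeps a uniform random subset of `round(fraction * d)` detections per
#' experiment (the evaluation protocol that compares both estimators
#' against a known full-data union).  Units that lose all their detections
#' are dropped.
#'
#' @param x a [DetectionMatrix-class].
#' @param fraction in (0, 1].
#' @param seed integer seed.
#' @return the downsampled [DetectionMatrix-class].
#' @export
downsampleMatrix <- function(x, fraction, seed) {
  stopifnot(is(x, "DetectionMatrix"), fraction > 0, fraction <= 1)
  if (fraction == 1) return(x)
  m <- detections(x)
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(m))) {
    hits <- which(m[, j] == 1L)
    keepN <- round(fraction * length(hits))
    drop <- hits[!seq_along(hits) %in%
                   sample.int(length(hits), keepN)]
    m[drop, j] <- 0L
  }
  keep <- rowSums(m) > 0L
  if (!any(keep)) stop("downsampling removed every detection")
  DetectionMatrix(m[keep, , drop = FALSE], unitLevel = unitLevel(x))
}
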