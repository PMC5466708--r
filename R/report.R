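## Per-species report: every labelled analysis of a compendium at both the
## protein and p-site level, Table-style, with NA (never zero, never a
## silent omission) where an analysis is unavailable or fails.

.roundHalfUp <- function(x) floor(x + 0.5)

#' Detection potential of the HTP technologies
#'
#' The fraction of the combined HTP+LTP population estimate that the
#' HTP-only estimate reaches, as a half-up-rounded integer percent:
#' `round(100 * htpEstimate / combinedEstimate)`.  Invariant under any
#' common scaling of the two estimates.
#'
#' @param htpEstimate abundance estimate from HTP data alone (typically
#'   the noise-adjusted capture-recapture estimate).
#' @param combinedEstimate abundance estimate incorporating the LTP
#'   compendium (typically the two-list estimate).
#' @return integer percent, or `NA` if either input is not finite.
#' @examples
#' detectionPotential(2772, 2951)  # 94
#' @export
detectionPotential <- function(htpEstimate, combinedEstimate) {
  if (!is.finite(htpEstimate) || !is.finite(combinedEstimate) ||
      combinedEstimate <= 0)
    return(NA_real_)
  .roundHalfUp(100 * htpEstimate / combinedEstimate)
}

.try_na <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(NA_real_, note = conditionMessage(e))
  })
}

.levelReport <- function(x, ltpUnits, noiseRate, cap, nInjections,
                         scalingFactor, seed, level) {
  est <- function(m) nHat(fitLoglinear(
    captureHistories(m, cap = cap), "MthChao"))
  cf <- function(curve) fitRecovery(curve, noiseTerm = TRUE,
                                    fixedC = noiseRate)@a

  current <- nrow(x)
  current3x <- .try_na(nrow(filterMinExperiments(x, 3L)))
  rcNoise <- .try_na(adjustForNoise(x, est, rate = noiseRate,
                                    nInjections = nInjections,
                                    seed = seed)@adjustedEstimate)
  rcHtpLtp <- if (is.null(ltpUnits)) NA_real_ else
    .try_na(nHat(petersenTwoList(unitIds(x), ltpUnits)))
  cfNoise <- .try_na(cf(buildCurve(x)))
  cf3x <- .try_na(cf(buildCurve(filterMinExperiments(x, 3L))))
  cfStart <- .try_na(cf(buildCurve(x, perturbOrder(x, "best_start"),
                                   orderingLabel = "best_start")))
  cfEnd <- .try_na(cf(buildCurve(x, perturbOrder(x, "best_end"),
                                 orderingLabel = "best_end")))
  cfHalf <- .try_na(cf(buildCurve(x, perturbOrder(x, "half_experiments"),
                                  orderingLabel = "half_experiments")))
  pot <- detectionPotential(rcNoise, rcHtpLtp)

  vals <- c(current = current, current_3X = current3x,
            Rcapture_HTP_vs_LTP = rcHtpLtp,
            Rcapture_noise_adjusted = rcNoise,
            CF_noise = cfNoise, CF_3X = cf3x,
            CF_best_start = cfStart, CF_best_end = cfEnd,
            CF_half_exp = cfHalf, detection_potential = pot)
  scaled <- vals * scalingFactor
  scaled["detection_potential"] <- pot   # ratio: scaling cancels
  data.frame(level = level, analysis = names(vals),
             raw = unname(vals), scaled = unname(scaled),
             row.names = NULL)
}

#' Build the per-species report at both analysis levels
#'
#' Runs every labelled analysis — observed counts, the 3X high-confidence
#' counts, the two-list HTP-vs-LTP capture-recapture estimate, the
#' noise-adjusted Chao Mth estimate on the `cap` largest datasets, and the
#' curve fits (fixed noise slope) under each ordering perturbation — on
#' the site-level matrix and on its protein-level collapse.  Any failing
#' sub-analysis is reported as `NA` (with the diagnostic attached as an
#' attribute), never aborting the report.
#'
#' The `scalingFactor` handles proteome-completeness corrections: when the
#' reference proteome annotation covers only part of the true proteome
#' (e.g. a well-annotated subset of ~16 000 of ~20 000 genes, corrected by
#' `scalingFactor = 1.25`), all estimates are scaled multiplicatively.
#' Both raw and scaled columns are emitted; the detection potential is a
#' ratio and is scaling-invariant.
#'
#' @param siteMatrix a site-level [DetectionMatrix-class] of HTP data.
#' @param ltpSites optional character vector of LTP p-site ids (same id
#'   convention); when absent the HTP-vs-LTP entries are `NA`.
#' @param ltpProteins optional character vector of LTP protein ids;
#'   derived from `ltpSites` when absent.
#' @param noiseRate assumed contamination level (default 0.01).
#' @param cap maximum datasets for the capture-recapture fits (default
#'   15).
#' @param nInjections noise-injection replicates (default 10).
#' @param scalingFactor proteome-completeness multiplier (default 1).
#' @param seed integer seed for the injection streams.
#' @return a data.frame with columns `level` (`"proteins"`, `"p_sites"`),
#'   `analysis`, `raw`, `scaled`.
#' @export
speciesReport <- function(siteMatrix, ltpSites = NULL, ltpProteins = NULL,
                          noiseRate = 0.01, cap = 15L, nInjections = 10L,
                          scalingFactor = 1, seed = 1L) {
  stopifnot(is(siteMatrix, "DetectionMatrix"),
            unitLevel(siteMatrix) == "site")
  protMatrix <- collapseToProteins(siteMatrix)
  if (is.null(ltpProteins) && !is.null(ltpSites))
    ltpProteins <- unique(sub("_[STY][0-9]+$", "", ltpSites))
  rbind(
    .levelReport(protMatrix, ltpProteins, noiseRate, cap, nInjections,
                 scalingFactor, seed, level = "proteins"),
    .levelReport(siteMatrix, ltpSites, noiseRate, cap, nInjections,
                 scalingFactor, seed, level = "p_sites"))
}

#' Downsampling evaluation of both estimators
#'
#' The validation protocol against a known target: every experiment is
#' randomly downsampled to `fraction` of its detections, then both the
#' AIC-selected capture-recapture estimate and the curve-fit asymptote are
#' computed on the reduced data and reported next to the full-data
#' non-redundant union (the known quantity both should approach).
#' Experiments emptied by downsampling are dropped with a warning.
#'
#' @param x a [DetectionMatrix-class] with at least 3 experiments.
#' @param fraction downsampling fraction (default 0.5).
#' @param seed integer seed.
#' @return list with `observedUnion` (full-data non-redundant count),
#'   `fraction`, `rcaptureEstimate`, `curvefitEstimate`,
#'   `downsampledUnion`, `seed`.
#' @export
evaluateByDownsampling <- function(x, fraction = 0.5, seed) {
  stopifnot(is(x, "DetectionMatrix"))
  if (ncol(x) < 3L) stop("evaluation needs at least 3 experiments")
  ds <- downsampleMatrix(x, fraction, seed = seed)
  empty <- colSums(detections(ds)) == 0L
  if (any(empty)) {
    warning("experiments emptied by downsampling dropped: ",
            paste(experimentIds(ds)[empty], collapse = ", "))
    ds <- DetectionMatrix(detections(ds)[, !empty, drop = FALSE],
                          unitLevel = unitLevel(ds))
    ds <- filterMinExperiments(ds, 1L)
  }
  rc <- nHat(selectModel(captureHistories(ds, cap = min(15L, ncol(ds)))))
  cfFit <- fitRecovery(buildCurve(ds))
  list(observedUnion = nrow(x), fraction = fraction,
       rcaptureEstimate = rc, curvefitEstimate = cfFit@a,
       downsampledUnion = nrow(ds), seed = as.integer(seed))
}

#' Published total-phosphoproteome estimates for four species
#'
#' A small bundled table of published estimates of total phosphoprotein
#' and p-site numbers for human, mouse, Arabidopsis and yeast under the
#' analyses this package implements (observed counts, 3X counts, two-list
#' HTP-vs-LTP capture-recapture, noise-assuming capture-recapture and
#' curve fits under order perturbations).  Used in examples and to
#' exercise [detectionPotential()] on real published numbers.
#'
#' @return data.frame with columns `species`, `level`, `analysis`,
#'   `value` (`NA` where the published analysis was unavailable).
#' @examples
#' pe <- publishedEstimates()
#' subset(pe, species == "yeast" & level == "proteins")
#' @export
publishedEstimates <- function() {
  path <- system.file("extdata", "published_phospho_estimates.csv",
                      package = "phosphoCensus", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
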