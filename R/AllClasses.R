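#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats glm poisson coef vcov logLik predict rbeta rbinom rlnorm
#'   runif setNames optim sd
#' @importFrom utils read.csv write.csv head
NULL

#' DetectionMatrix: binary units-by-experiments incidence table
#'
#' The universal input of the package: one row per unit (a phosphorylation
#' site, identified as `<protein>_<residue><position>`, or a bare protein id),
#' one column per experiment (conventionally named by the PubMed id of the
#' source dataset), with 1/0 cells for detected/not detected.  The class
#' extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `"detections"` assay and records whether rows are sites or proteins.
#'
#' Column order is meaningful: it is taken to be the chronological
#' (publication) order of the experiments, and every ordering-sensitive
#' analysis in the package uses it as the default.
#'
#' Validity requires: every cell 0 or 1, no all-zero rows (a unit must have
#' been detected at least once to appear), and unique unit and experiment ids.
#'
#' @slot unitLevel either `"site"` or `"protein"`.
#'
#' @seealso [DetectionMatrix()] for construction from a plain matrix,
#'   [readDetectionMatrix()] for the CSV format.
#' @export
setClass("DetectionMatrix",
  contains = "SummarizedExperiment",
  slots = c(unitLevel = "character")
)

setValidity("DetectionMatrix", function(object) {
  msg <- character()
  if (!(length(object@unitLevel) == 1L &&
        object@unitLevel %in% c("site", "protein")))
    msg <- c(msg, "unitLevel must be \"site\" or \"protein\"")
  if (!"detections" %in% SummarizedExperiment::assayNames(object))
    return(c(msg, "assay \"detections\" is missing"))
  m <- SummarizedExperiment::assay(object, "detections")
  if (!all(m %in% c(0L, 1L)))
    msg <- c(msg, "detection cells must all be 0 or 1")
  if ((nrow(object) > 0L && is.null(rownames(object))) ||
      (ncol(object) > 0L && is.null(colnames(object))))
    msg <- c(msg, "unit and experiment ids are required as dimnames")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate unit ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate experiment ids")
  if (nrow(m) > 0L) {
    zero <- rownames(object)[rowSums(m) == 0L]
    if (length(zero))
      msg <- c(msg, paste0("units with no detections: ",
                           paste(head(zero, 5L), collapse = ", "),
                           if (length(zero) > 5L) ", ..."))
  }
  if (length(msg)) msg else TRUE
})

#' JaccardSummary: pairwise experiment overlap
#'
#' Result of [jaccardQC()]: the full experiment-by-experiment Jaccard
#' similarity matrix together with the mean and maximum off-diagonal
#' similarity, the two numbers used to decide whether any pair of
#' experiments is similar enough to inflate the apparent saturation.
#'
#' @slot similarity symmetric numeric matrix, unit diagonal, values in
#'   `[0, 1]`.
#' @slot meanSimilarity mean off-diagonal similarity.
#' @slot maxSimilarity maximum off-diagonal similarity.
#' @export
setClass("JaccardSummary",
  slots = c(similarity = "matrix",
            meanSimilarity = "numeric",
            maxSimilarity = "numeric")
)

#' SaturationCurve: cumulative non-redundant vs redundant identifications
#'
#' One point per experiment processed (plus the origin): after experiment i,
#' x is the cumulative number of redundant detections over experiments 1..i
#' and y the cumulative number of distinct units seen so far.  The curve's
#' plateau is what the recovery model estimates.
#'
#' @slot points data.frame with columns `x`, `y`, including the `(0, 0)`
#'   anchor as its first row.
#' @slot orderingLabel one of `"chronological"`, `"best_start"`,
#'   `"best_end"`, `"half_experiments"`, or `"custom"`.
#' @slot experimentIds the experiment order the curve was built from.
#' @export
setClass("SaturationCurve",
  slots = c(points = "data.frame",
            orderingLabel = "character",
            experimentIds = "character")
)

setValidity("SaturationCurve", function(object) {
  p <- object@points
  if (!all(c("x", "y") %in% names(p)))
    return("points must have columns x and y")
  if (any(diff(p$x) < 0) || any(diff(p$y) < 0))
    return("x and y must be non-decreasing")
  if (any(p$y > p$x + 1e-9))
    return("y (non-redundant) cannot exceed x (redundant)")
  TRUE
})

#' RecoveryFit: fitted exponential recovery model
#'
#' Least-squares fit of y = a (1 - exp(-x/b)) (+ c x) to a
#' [SaturationCurve]. `a` is the asymptote, i.e. the estimated total number
#' of non-redundant units; `b` is the number of redundant detections needed
#' to recover 63.2% (1 - 1/e) of them; `c`, when present, is the average
#' per-detection false-positive rate accumulating linearly.
#'
#' @slot a asymptote (estimated total non-redundant units).
#' @slot b steepness constant (redundant detections to the 63.2% point).
#' @slot c linear noise slope; `NA` when the model has no noise term.
#' @slot cFixed TRUE when `c` was held fixed rather than estimated.
#' @slot sse sum of squared errors at the optimum.
#' @slot converged optimizer convergence flag.
#' @slot nPoints number of fitted points (including the origin anchor).
#' @slot orderingLabel ordering of the curve the fit came from.
#' @export
setClass("RecoveryFit",
  slots = c(a = "numeric", b = "numeric", c = "numeric",
            cFixed = "logical", sse = "numeric", converged = "logical",
            nPoints = "integer", orderingLabel = "character")
)

#' CaptureHistoryTable: frequencies of observable capture histories
#'
#' For t capture occasions (experiments) there are 2^t - 1 observable
#' detection patterns; the all-zero pattern is unobservable and its mass is
#' what closed-population estimators infer.  Frequencies are stored for
#' every observable pattern (zeros included) in pattern-code order
#' (pattern code = sum over occasions j of bit_j * 2^(j-1)).
#'
#' @slot t number of occasions.
#' @slot frequencies integer vector of length 2^t - 1, named by the t-bit
#'   pattern string (occasion 1 leftmost).
#' @slot n total observed units, `sum(frequencies)`.
#' @slot experimentIds the occasions, in occasion order.
#' @export
setClass("CaptureHistoryTable",
  slots = c(t = "integer", frequencies = "integer", n = "integer",
            experimentIds = "character")
)

setValidity("CaptureHistoryTable", function(object) {
  if (object@t < 2L) return("at least 2 capture occasions are required")
  if (length(object@frequencies) != 2L^object@t - 1L)
    return("frequencies must have length 2^t - 1")
  if (any(object@frequencies < 0L)) return("negative frequency")
  if (sum(object@frequencies) != object@n)
    return("n must equal sum(frequencies)")
  TRUE
})

#' AbundanceEstimate: estimated total population size
#'
#' Result of a closed-population fit: the estimated total number of units
#' (observed plus unseen), its asymptotic standard error, and for loglinear
#' models the AIC and fitted coefficients.  For loglinear models
#' `nHat = nObserved + exp(beta0)`, with `beta0` the intercept, i.e. the
#' log expected count of the unobservable all-zero history.
#'
#' @slot model one of `"M0"`, `"Mt"`, `"MhChao"`, `"MthChao"`, `"Petersen"`.
#' @slot nHat estimated total population size.
#' @slot se asymptotic standard error of `nHat`.
#' @slot aic AIC of the loglinear fit (`NA` for Petersen).
#' @slot nObserved number of distinct units observed.
#' @slot coefficients fitted loglinear coefficients (intercept, occasion
#'   effects, heterogeneity terms), or the Petersen ingredients.
#' @slot details list with fit diagnostics (dropped heterogeneity terms,
#'   Chapman-corrected estimate for Petersen, deviances, ...).
#' @export
setClass("AbundanceEstimate",
  slots = c(model = "character", nHat = "numeric", se = "numeric",
            aic = "numeric", nObserved = "integer",
            coefficients = "numeric", details = "list")
)

setValidity("AbundanceEstimate", function(object) {
  if (is.finite(object@nHat) && object@nHat < object@nObserved - 1e-6)
    return("nHat cannot be below the number of observed units")
  if (is.finite(object@se) && object@se < 0) return("negative se")
  TRUE
})

#' JackknifeSummary: abundance estimates over resampled experiment subsets
#'
#' Summary of repeated Chao Mth estimation on random subsets of the eligible
#' experiments: per-replicate estimates, their mean, standard deviation and
#' coefficient of variation.
#'
#' @slot replicates per-replicate `nHat` values.
#' @slot mean,sd,cv summary statistics over replicates (cv = sd/mean).
#' @slot nReps number of replicates.
#' @slot subsetSize experiments drawn per replicate.
#' @slot eligibilityThreshold minimum detections for an experiment to enter
#'   the sampling pool.
#' @slot seed master seed.
#' @export
setClass("JackknifeSummary",
  slots = c(replicates = "numeric", mean = "numeric", sd = "numeric",
            cv = "numeric", nReps = "integer", subsetSize = "integer",
            eligibilityThreshold = "integer", seed = "integer")
)

#' NoiseAdjustment: downward correction of an abundance estimate
#'
#' Records the noise-injection experiment behind a corrected estimate: the
#' original estimate, the estimates on matrices with stochastic
#' false-positives injected at `noiseRate`, the mean inflation `delta`, and
#' the adjusted estimate `original - delta`.  The correction assumes the
#' inflation caused by injecting k% noise equals the inflation caused by the
#' k% noise already present (linear extrapolation).
#'
#' @slot noiseRate injected false-positive rate per experiment.
#' @slot originalEstimate estimate on the input matrix.
#' @slot inflatedEstimates estimates on the injection replicates.
#' @slot delta mean(inflatedEstimates) - originalEstimate.
#' @slot adjustedEstimate originalEstimate - delta.
#' @slot nInjections number of injection replicates kept.
#' @slot seed master seed.
#' @export
setClass("NoiseAdjustment",
  slots = c(noiseRate = "numeric", originalEstimate = "numeric",
            inflatedEstimates = "numeric", delta = "numeric",
            adjustedEstimate = "numeric", nInjections = "integer",
            seed = "integer")
)
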