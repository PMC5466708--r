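## Closed-population capture-recapture via loglinear (Poisson) models on
## capture-history frequencies.  N-hat = n + exp(beta0): the intercept is
## the log expected count of the unobservable all-zero history, since every
## design covariate vanishes on it.

# t-bit patterns for codes 1 .. 2^t - 1, occasion j in column j
.historyBits <- function(t) {
  codes <- seq_len(2L^t - 1L)
  bits <- matrix(as.integer(intToBits(codes)), nrow = 32L)[seq_len(t), ,
                                                           drop = FALSE]
  t(bits)
}

.patternNames <- function(bits) apply(bits, 1L, paste, collapse = "")

#' Capture-history frequencies from a detection matrix
#'
#' Treats each experiment as a capture occasion and each unit's detection
#' pattern as its capture history.  When more than `cap` experiments are
#' supplied, the `cap` largest (by detection count, ties broken by earliest
#' column) are kept — loglinear closed-population fits handle roughly 15-20
#' occasions before the 2^t history space becomes unmanageable, and the
#' headline analyses use the 15 largest datasets.  Units absent from every
#' kept experiment drop out of the observed count.
#'
#' @param x a [DetectionMatrix-class].
#' @param experiments experiment ids to use (default: all).
#' @param cap maximum number of occasions, default 15, hard ceiling 20.
#' @return a [CaptureHistoryTable-class].
#' @examples
#' dm <- DetectionMatrix(
#'   matrix(c(1, 1, 0, 0, 1, 1), 3,
#'          dimnames = list(c("u1", "u2", "u3"), c("A", "B"))),
#'   unitLevel = "protein")
#' captureHistories(dm)@frequencies
#' @export
captureHistories <- function(x, experiments = experimentIds(x), cap = 15L) {
  stopifnot(is(x, "DetectionMatrix"))
  if (cap > 20L)
    stop("cap above 20 occasions: 2^t history space is unmanageable")
  unknown <- setdiff(experiments, experimentIds(x))
  if (length(unknown))
    stop("unknown experiment ids: ", paste(unknown, collapse = ", "))
  m <- detections(x)[, experiments, drop = FALSE]
  if (ncol(m) > cap) {
    keep <- order(-colSums(m), seq_len(ncol(m)))[seq_len(cap)]
    keep <- sort(keep)                       # keep chronological order
    m <- m[, keep, drop = FALSE]
  }
  t <- ncol(m)
  if (t < 2L) stop("at least two capture occasions are required")
  codes <- as.integer(m %*% 2L^(seq_len(t) - 1L))
  freq <- as.integer(tabulate(codes, nbins = 2L^t - 1L))
  names(freq) <- .patternNames(.historyBits(t))
  new("CaptureHistoryTable", t = t, frequencies = freq,
      n = sum(freq), experimentIds = colnames(m))
}

setMethod("show", "CaptureHistoryTable", function(object) {
  cat("CaptureHistoryTable: t =", object@t, "occasions, n =",
      object@n, "observed units\n")
  cat("  non-zero histories:", sum(object@frequencies > 0L), "of",
      length(object@frequencies), "\n")
})

# Design matrix (without intercept) for each model; eta columns are
# indicators 1{captures >= j}, j = 3..t, Chao's lower-bound terms.
.cpDesign <- function(bits, model) {
  t <- ncol(bits)
  s <- rowSums(bits)
  eta <- NULL
  if (model %in% c("MhChao", "MthChao")) {
    if (t < 3L) stop("Chao heterogeneity models need at least 3 occasions")
    eta <- vapply(3:t, function(j) as.numeric(s >= j), numeric(nrow(bits)))
    eta <- matrix(eta, nrow = nrow(bits))
    colnames(eta) <- paste0("eta", 3:t)
  }
  X <- switch(model,
    M0 = cbind(s = s),
    Mt = structure(bits + 0, dimnames = list(NULL, paste0("occ", seq_len(t)))),
    MhChao = cbind(s = s, eta),
    MthChao = cbind(structure(bits + 0,
                              dimnames = list(NULL, paste0("occ", seq_len(t)))),
                    eta))
  X
}

#' Fit a loglinear closed-population model to capture histories
#'
#' Fits a log-link Poisson count model to the 2^t - 1 observable history
#' frequencies by iteratively reweighted least squares.  Design by model:
#' `M0` intercept + number of captures; `Mt` intercept + one indicator per
#' occasion; `MhChao` intercept + captures + non-negative heterogeneity
#' terms eta_j = 1(captures >= j), j = 3..t (Chao's lower-bound
#' parameterization); `MthChao` the union of the Mt and heterogeneity
#' columns.  The population estimate is `nHat = n + exp(beta0)`, its SE by
#' the delta method on the fitted covariance, and AIC is
#' `-2 loglik + 2 npar` of the count model.
#'
#' A heterogeneity term estimated negative violates the lower-bound
#' constraint; it is dropped and the model refit, with the dropped terms
#' recorded in `details$droppedEta`.
#'
#' @param h a [CaptureHistoryTable-class].
#' @param model one of `"M0"`, `"Mt"`, `"MhChao"`, `"MthChao"`.
#' @return an [AbundanceEstimate-class].
#' @examples
#' dm <- DetectionMatrix(
#'   matrix(c(1, 1, 0, 0, 1, 1), 3,
#'          dimnames = list(c("u1", "u2", "u3"), c("A", "B"))),
#'   unitLevel = "protein")
#' fitLoglinear(captureHistories(dm), "Mt")
#' @export
fitLoglinear <- function(h, model = c("MthChao", "M0", "Mt", "MhChao")) {
  stopifnot(is(h, "CaptureHistoryTable"))
  model <- match.arg(model)
  bits <- .historyBits(h@t)
  y <- h@frequencies
  X <- .cpDesign(bits, model)
  dropped <- character()
  repeat {
    fit <- glm(y ~ X, family = poisson(),
               control = list(epsilon = 1e-10, maxit = 200))
    if (!fit$converged)
      stop("IRLS did not converge for model ", model,
           " (", fit$iter, " iterations)")
    co <- coef(fit)
    etaIdx <- grep("eta", names(co))
    bad <- etaIdx[!is.na(co[etaIdx]) & co[etaIdx] < -1e-8]
    if (!length(bad)) break
    badNames <- sub("^X", "", names(co)[bad])
    dropped <- c(dropped, badNames)
    X <- X[, setdiff(colnames(X), badNames), drop = FALSE]
  }
  co <- coef(fit)
  if (anyNA(co)) co <- co[!is.na(co)]
  b0 <- co[["(Intercept)"]]
  mu0 <- exp(b0)
  se <- mu0 * sqrt(vcov(fit)[1L, 1L])
  names(co) <- sub("^X", "", names(co))
  new("AbundanceEstimate", model = model,
      nHat = h@n + mu0, se = se, aic = fit$aic,
      nObserved = as.integer(h@n), coefficients = co,
      details = list(droppedEta = dropped,
                     deviance = fit$deviance,
                     nullDeviance = fit$null.deviance,
                     logLik = as.numeric(logLik(fit)),
                     nParameters = length(co)))
}

#' Accessors for AbundanceEstimate
#'
#' @param x an [AbundanceEstimate-class].
#' @return `nHat()` the estimated total population size; `modelName()` the
#'   model label.
#' @name AbundanceEstimate-accessors
#' @aliases nHat modelName
NULL

#' @rdname AbundanceEstimate-accessors
#' @export
setMethod("nHat", "AbundanceEstimate", function(x) x@nHat)

#' @rdname AbundanceEstimate-accessors
#' @export
setMethod("modelName", "AbundanceEstimate", function(x) x@model)

setMethod("show", "AbundanceEstimate", function(object) {
  cat("AbundanceEstimate [", object@model, "]\n", sep = "")
  cat(sprintf("  N-hat = %.1f (SE %.1f), observed n = %d\n",
              object@nHat, object@se, object@nObserved))
  if (is.finite(object@aic)) cat(sprintf("  AIC = %.2f\n", object@aic))
})

#' AIC-based model selection over the closed-population models
#'
#' Fits M0, Mt, MhChao and MthChao to the same history table and returns
#' the minimum-AIC estimate (ties broken toward the model with fewer
#' parameters).  Models that fail to fit are dropped; if all fail the
#' per-model diagnostics are aggregated into the error.
#'
#' @param h a [CaptureHistoryTable-class] with at least 3 occasions.
#' @return the selected [AbundanceEstimate-class]; all four fits are kept
#'   in `details$allFits`.
#' @export
selectModel <- function(h) {
  stopifnot(is(h, "CaptureHistoryTable"))
  if (h@t < 3L) stop("model selection needs at least 3 occasions")
  models <- c("M0", "Mt", "MhChao", "MthChao")
  fits <- lapply(models, function(mod)
    tryCatch(fitLoglinear(h, mod), error = function(e) e))
  ok <- vapply(fits, is, logical(1L), "AbundanceEstimate")
  if (!any(ok))
    stop("all closed-population fits failed: ",
         paste(vapply(fits, conditionMessage, character(1L)),
               collapse = " | "))
  fits <- fits[ok]
  aics <- vapply(fits, function(f) f@aic, numeric(1L))
  npars <- vapply(fits, function(f) f@details$nParameters, numeric(1L))
  best <- fits[[order(aics, npars)[1L]]]
  best@details$allFits <- setNames(fits, vapply(fits, modelName,
                                                character(1L)))
  best
}

#' Two-list Petersen estimator
#'
#' The closed-form two-sample estimator used for the merged HTP-vs-LTP
#' analysis: `nHat = n1 n2 / m` with `m` the overlap, SE from the standard
#' Petersen variance `n1 n2 (n1 - m)(n2 - m) / m^3`.  The Chapman-corrected
#' variant `(n1 + 1)(n2 + 1)/(m + 1) - 1` is reported in
#' `details$chapman`.  With two occasions this is exactly what the Mt
#' loglinear model estimates.
#'
#' @param list1,list2 character vectors of unit ids (e.g. the merged HTP
#'   and the LTP compendium).
#' @return an [AbundanceEstimate-class] with model `"Petersen"`.
#' @examples
#' petersenTwoList(paste0("u", 1:100), paste0("u", 76:125))  # N-hat = 200
#' @export
petersenTwoList <- function(list1, list2) {
  list1 <- unique(as.character(list1))
  list2 <- unique(as.character(list2))
  n1 <- as.numeric(length(list1)); n2 <- as.numeric(length(list2))
  m <- as.numeric(length(intersect(list1, list2)))
  if (m == 0L) stop("disjoint lists: Petersen estimate undefined")
  nHat <- n1 * n2 / m
  se <- sqrt(n1 * n2 * (n1 - m) * (n2 - m) / m^3)
  new("AbundanceEstimate", model = "Petersen",
      nHat = nHat, se = se, aic = NA_real_,
      nObserved = as.integer(n1 + n2 - m),
      coefficients = c(n1 = n1, n2 = n2, m = m),
      details = list(chapman = (n1 + 1) * (n2 + 1) / (m + 1) - 1))
}

#' Jackknife resampling of the Chao Mth estimate
#'
#' Repeatedly draws `subsetSize` experiments (without replacement, uniform)
#' from those with at least `eligibilityThreshold` detections, fits the
#' Chao Mth model on each subset, and summarizes the estimates by mean,
#' standard deviation and coefficient of variation.  Each replicate uses a
#' deterministic seed stream derived from the master seed, so individual
#' replicates are independently reproducible.
#'
#' @param x a [DetectionMatrix-class].
#' @param eligibilityThreshold minimum detections per experiment
#'   (default 500).
#' @param subsetSize experiments per replicate (default 15).
#' @param nReps number of replicates (default 100).
#' @param seed master seed (integer).
#' @return a [JackknifeSummary-class].
#' @export
jackknifeAbundance <- function(x, eligibilityThreshold = 500L,
                               subsetSize = 15L, nReps = 100L, seed) {
  stopifnot(is(x, "DetectionMatrix"))
  sizes <- colSums(detections(x))
  eligible <- experimentIds(x)[sizes >= eligibilityThreshold]
  if (length(eligible) < subsetSize)
    stop("only ", length(eligible), " experiments meet the ",
         eligibilityThreshold, "-detection threshold (need ",
         subsetSize, ")")
  set.seed(as.integer(seed))
  repSeeds <- sample.int(.Machine$integer.max, nReps)
  reps <- vapply(seq_len(nReps), function(r) {
    set.seed(repSeeds[r])
    sub <- sample(eligible, subsetSize)
    sub <- eligible[sort(match(sub, eligible))]   # keep chronological order
    h <- captureHistories(x, experiments = sub, cap = subsetSize)
    nHat(fitLoglinear(h, "MthChao"))
  }, numeric(1L))
  sdv <- if (nReps > 1L) sd(reps) else {
    warning("sd undefined with a single replicate; reported as 0")
    0
  }
  new("JackknifeSummary", replicates = reps, mean = mean(reps),
      sd = sdv, cv = sdv / mean(reps), nReps = as.integer(nReps),
      subsetSize = as.integer(subsetSize),
      eligibilityThreshold = as.integer(eligibilityThreshold),
      seed = as.integer(seed))
}

setMethod("show", "JackknifeSummary", function(object) {
  cat("JackknifeSummary:", object@nReps, "replicates of",
      object@subsetSize, "experiments\n")
  cat(sprintf("  N-hat mean = %.1f, sd = %.1f, cv = %.3f\n",
              object@mean, object@sd, object@cv))
})
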