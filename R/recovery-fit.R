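#' Fit the exponential recovery model to a saturation curve
#'
#' Least-squares fit of
#' \deqn{y = a (1 - e^{-x/b})}{y = a (1 - exp(-x/b))}
#' or, with the noise term,
#' \deqn{y = a (1 - e^{-x/b}) + c x}{y = a (1 - exp(-x/b)) + c x}
#' to the (x, y) points of a [SaturationCurve-class].  `a` estimates the
#' total number of non-redundant true-positive units; `b` is the number of
#' redundant detections at which the pure-recovery component reaches
#' 63.2% (1 - 1/e) of `a`; `c` models false positives that, being nearly
#' non-overlapping between experiments, keep accumulating linearly while
#' true discoveries plateau.
#'
#' The noise slope can either be estimated freely or held at a stated
#' contamination level (e.g. `fixedC = 0.01` for the "1% noise" analyses,
#' the default interpretation used throughout the reporting functions).
#'
#' Optimization is bounded nonlinear least squares
#' ([minpack.lm::nlsLM()] with Levenberg-Marquardt, L-BFGS-B fallback) on
#' SSE, with bounds `b` in `(0, 100 max(x)]`, `c` in `[0, 1]`, and `a` in
#' `[max(y), 100 max(y)]` for the pure model — the asymptote cannot sit
#' below the observed non-redundant count — relaxed downwards for noise
#' fits, where part of the observed count is linear contamination.  The
#' start is `a0 = 1.2 max(y)`, `b0 = max(x)/3`, `c0 = 0.01` unless `init`
#' is given.
#'
#' @param curve a [SaturationCurve-class]; at least 3 points beyond the
#'   origin are needed without the noise term, 4 with it (when `c` is
#'   estimated).
#' @param noiseTerm include the linear `c x` term?
#' @param fixedC if non-NULL (and `noiseTerm = TRUE`), hold `c` at this
#'   value instead of estimating it.
#' @param init optional named list/vector with any of `a`, `b`, `c`
#'   overriding the default start.
#' @param anchorOrigin include the (0, 0) point in the fit (default TRUE).
#' @return a [RecoveryFit-class].
#' @examples
#' xs <- seq(1000, 20000, by = 1000)
#' cv <- new("SaturationCurve",
#'           points = data.frame(x = c(0, xs),
#'                               y = c(0, 1000 * (1 - exp(-xs / 5000)))),
#'           orderingLabel = "chronological", experimentIds = character())
#' fit <- fitRecovery(cv)
#' c(a = fit@a, b = fit@b)
#' @export
fitRecovery <- function(curve, noiseTerm = FALSE, fixedC = NULL,
                        init = NULL, anchorOrigin = TRUE) {
  stopifnot(is(curve, "SaturationCurve"))
  pts <- curvePoints(curve)
  if (!anchorOrigin) pts <- pts[!(pts$x == 0 & pts$y == 0), , drop = FALSE]
  freeC <- noiseTerm && is.null(fixedC)
  nPar <- if (freeC) 3L else 2L
  if (nrow(pts) - 1L < nPar + 1L - !anchorOrigin)
    stop("insufficient saturation data: ", nrow(pts),
         " points for a ", nPar, "-parameter model")
  xv <- pts$x; yv <- pts$y
  maxY <- max(yv); maxX <- max(xv)
  if (maxY <= 0) stop("degenerate curve: no detections")
  start <- list(a = 1.2 * maxY, b = maxX / 3, c = 0.01)
  if (!is.null(init)) start[names(init)] <- as.list(init)
  cfix <- if (noiseTerm && !is.null(fixedC)) fixedC else 0
  # without noise the asymptote cannot sit below the observed final count;
  # with a noise term part of the final count is linear contamination, so
  # the true-positive asymptote may be smaller
  aLow <- if (noiseTerm) max(maxY - maxX, 1e-3 * maxY) else maxY
  lower <- c(a = aLow, b = maxX * 1e-6)
  upper <- c(a = 100 * maxY, b = 100 * maxX)
  if (freeC) {
    lower <- c(lower, c = 0); upper <- c(upper, c = 1)
  }

  model <- if (freeC) {
    y ~ a * (1 - exp(-x / b)) + c * x
  } else {
    y ~ a * (1 - exp(-x / b)) + cfix * x
  }
  dat <- data.frame(x = xv, y = yv, cfix = cfix)
  start <- start[names(lower)]

  fit <- tryCatch(
    minpack.lm::nlsLM(model, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- coef(fit)
    converged <- fit$convInfo$isConv %||% TRUE
  } else {
    # L-BFGS-B fallback directly on the SSE surface
    sse <- function(p) {
      yy <- p[["a"]] * (1 - exp(-xv / p[["b"]])) +
        (if (freeC) p[["c"]] else cfix) * xv
      sum((yv - yy)^2)
    }
    o <- optim(unlist(start), sse, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 10000, factr = 10))
    est <- o$par
    converged <- o$convergence == 0
  }
  a <- unname(est[["a"]]); b <- unname(est[["b"]])
  cc <- if (freeC) unname(est[["c"]]) else cfix
  yfit <- a * (1 - exp(-xv / b)) + cc * xv
  if (!converged)
    warning("recovery fit did not satisfy convergence tolerance; ",
            "parameters reported anyway")
  new("RecoveryFit", a = a, b = b,
      c = if (noiseTerm) cc else NA_real_,
      cFixed = noiseTerm && !is.null(fixedC),
      sse = sum((yv - yfit)^2), converged = converged,
      nPoints = nrow(pts), orderingLabel = curve@orderingLabel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted non-redundant count at a given redundant count
#'
#' Evaluates the fitted recovery model: `a (1 - exp(-x/b))`, plus `c x`
#' when the fit includes the noise term.  At `x = 0` the prediction is 0;
#' without the noise term it approaches `a` from below as `x` grows, and at
#' `x = b` the pure-recovery component is exactly `(1 - 1/e) a`, i.e.
#' 63.2% of the asymptote.
#'
#' @param object a [RecoveryFit-class].
#' @param x non-negative redundant detection count(s).
#' @param ... unused.
#' @return predicted cumulative non-redundant count(s).
#' @export
setMethod("predict", "RecoveryFit", function(object, x, ...) {
  stopifnot(all(x >= 0))
  out <- object@a * (1 - exp(-x / object@b))
  if (!is.na(object@c)) out <- out + object@c * x
  out
})

setMethod("show", "RecoveryFit", function(object) {
  cat("RecoveryFit (", object@orderingLabel, " ordering, ",
      object@nPoints, " points)\n", sep = "")
  cat(sprintf("  a (total units) = %.1f\n", object@a))
  cat(sprintf("  b (63.2%% point) = %.1f\n", object@b))
  if (!is.na(object@c))
    cat(sprintf("  c (noise slope) = %.4g%s\n", object@c,
                if (object@cFixed) " [fixed]" else ""))
  cat(sprintf("  SSE = %.4g | converged: %s\n",
              object@sse, object@converged))
})
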