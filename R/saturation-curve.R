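#' Build the saturation curve from an ordered sequence of experiments
#'
#' Processes experiments in the given order and records, after each one,
#' the cumulative number of redundant detections (x) and of distinct units
#' seen so far (y).  The origin (0, 0) is included as a fit anchor: the
#' recovery model passes through it, and anchoring stabilizes fits with few
#' experiments.  The final point is order-invariant; only the path depends
#' on the ordering.
#'
#' @param x a [DetectionMatrix-class].
#' @param order character vector of experiment ids, a permutation of a
#'   subset of `experimentIds(x)`; defaults to the column (chronological)
#'   order.
#' @param orderingLabel label stored on the curve; inferred as
#'   `"chronological"` when `order` is the column order, `"custom"`
#'   otherwise.
#' @return a [SaturationCurve-class].
#' @examples
#' dm <- DetectionMatrix(
#'   matrix(c(1, 1, 0, 0, 1, 1), 3,
#'          dimnames = list(c("a", "b", "c"), c("e1", "e2"))),
#'   unitLevel = "protein")
#' curvePoints(buildCurve(dm))
#' @export
buildCurve <- function(x, order = experimentIds(x), orderingLabel = NULL) {
  stopifnot(is(x, "DetectionMatrix"))
  unknown <- setdiff(order, experimentIds(x))
  if (length(unknown))
    stop("unknown experiment ids in order: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(order)) stop("duplicated experiment ids in order")
  if (is.null(orderingLabel))
    orderingLabel <- if (identical(order, experimentIds(x)))
      "chronological" else "custom"
  m <- detections(x)[, order, drop = FALSE]
  xs <- cumsum(colSums(m))
  # y_i = |union of units over experiments 1..i|
  cum <- t(apply(m, 1L, cummax))
  if (length(order) == 1L) cum <- matrix(m, ncol = 1L)
  ys <- colSums(cum)
  new("SaturationCurve",
      points = data.frame(x = c(0, unname(xs)), y = c(0, unname(ys))),
      orderingLabel = orderingLabel,
      experimentIds = as.character(order))
}

#' Accessors for SaturationCurve
#'
#' @param x a [SaturationCurve-class].
#' @return `curvePoints()` the data.frame of (x, y) points;
#'   `orderingLabel()` the ordering the curve was built under.
#' @name SaturationCurve-accessors
#' @aliases curvePoints orderingLabel
NULL

#' @rdname SaturationCurve-accessors
#' @export
setMethod("curvePoints", "SaturationCurve", function(x) x@points)

#' @rdname SaturationCurve-accessors
#' @export
setMethod("orderingLabel", "SaturationCurve", function(x) x@orderingLabel)

setMethod("show", "SaturationCurve", function(object) {
  p <- object@points
  cat("SaturationCurve (", object@orderingLabel, "): ",
      length(object@experimentIds), " experiments\n", sep = "")
  cat("  final point: x =", p$x[nrow(p)], ", y =", p$y[nrow(p)], "\n")
})

#' Experiment orderings for robustness perturbations
#'
#' The curve-fit estimates could depend on the order in which experiments
#' were published.  The perturbations move the single largest experiment
#' (by detection count; ties broken by earliest column) to the front
#' (`best_start`) or back (`best_end`) of the chronological order, or keep
#' only the first half, `ceiling(t/2)` experiments (`half_experiments`).
#'
#' @param x a [DetectionMatrix-class].
#' @param mode one of `"chronological"`, `"best_start"`, `"best_end"`,
#'   `"half_experiments"`.
#' @return character vector of experiment ids in the perturbed order.
#' @export
perturbOrder <- function(x, mode = c("chronological", "best_start",
                                     "best_end", "half_experiments")) {
  stopifnot(is(x, "DetectionMatrix"))
  mode <- match.arg(mode)
  ids <- experimentIds(x)
  if (mode == "chronological") return(ids)
  if (mode == "half_experiments") return(ids[seq_len(ceiling(length(ids) / 2))])
  big <- which.max(colSums(detections(x)))  # which.max: earliest on ties
  rest <- ids[-big]
  if (mode == "best_start") c(ids[big], rest) else c(rest, ids[big])
}

#' Export a saturation curve as CSV
#'
#' Two-column (x, y) CSV for plotting, with the ordering recorded in a
#' leading comment line.
#'
#' @param x a [SaturationCurve-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(x, path) {
  stopifnot(is(x, "SaturationCurve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ordering: ", x@orderingLabel), con)
  write.csv(x@points, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
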