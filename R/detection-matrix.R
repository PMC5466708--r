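#' Construct a DetectionMatrix from a binary matrix
#'
#' @param detections integer/numeric matrix of 0/1 cells with unit ids as
#'   rownames and experiment ids as colnames. Column order is kept and is
#'   interpreted as chronological publication order.
#' @param unitLevel `"site"` (rows are phosphorylation sites named
#'   `<protein>_<residue><position>`, residue one of S/T/Y, position
#'   1-based) or `"protein"` (rows are bare protein ids).
#'
#' @return a validated [DetectionMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
#'             dimnames = list(c("P1_S10", "P1_T20", "P2_S5"),
#'                             c("11111111", "22222222")))
#' dm <- DetectionMatrix(m, unitLevel = "site")
#' dm
#' @export
DetectionMatrix <- function(detections, unitLevel = c("site", "protein")) {
  unitLevel <- match.arg(unitLevel)
  detections <- as.matrix(detections)
  storage.mode(detections) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(detections = detections))
  new("DetectionMatrix", se, unitLevel = unitLevel)
}

#' Accessors for DetectionMatrix
#'
#' `detections()` returns the binary incidence matrix, `unitIds()` and
#' `experimentIds()` its dimnames, `unitLevel()` whether rows are sites or
#' proteins.
#'
#' @param x a [DetectionMatrix-class].
#' @return see individual descriptions.
#' @name DetectionMatrix-accessors
#' @aliases detections unitIds experimentIds unitLevel
NULL

#' @rdname DetectionMatrix-accessors
#' @export
setMethod("detections", "DetectionMatrix", function(x)
  SummarizedExperiment::assay(x, "detections"))

#' @rdname DetectionMatrix-accessors
#' @export
setMethod("unitIds", "DetectionMatrix", function(x) rownames(x))

#' @rdname DetectionMatrix-accessors
#' @export
setMethod("experimentIds", "DetectionMatrix", function(x) colnames(x))

#' @rdname DetectionMatrix-accessors
#' @export
setMethod("unitLevel", "DetectionMatrix", function(x) x@unitLevel)

setMethod("show", "DetectionMatrix", function(object) {
  cat("DetectionMatrix (", object@unitLevel, " level): ",
      nrow(object), " units x ", ncol(object), " experiments\n", sep = "")
  cat("  detections:", sum(detections(object)),
      "| per-experiment range:",
      paste(range(colSums(detections(object))), collapse = "-"), "\n")
})

#' Read a detection matrix from CSV
#'
#' The expected format mirrors the supplementary layout of published
#' phosphoproteomics compendia: a header row of experiment ids (PubMed ids
#' by convention) with first column `unit_id`, then one row per unit with
#' 0/1 cells; empty cells are read as 0.  Column order in the file is kept
#' and treated as chronological.
#'
#' @param path CSV file path.
#' @inheritParams DetectionMatrix
#' @return a validated [DetectionMatrix-class].
#' @seealso [writeDetectionMatrix()] for the inverse; the round trip is
#'   exact.
#' @export
readDetectionMatrix <- function(path, unitLevel = c("site", "protein")) {
  unitLevel <- match.arg(unitLevel)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("matrix CSV needs a unit_id column plus at least one experiment")
  ids <- df[[1L]]
  expIds <- colnames(df)[-1L]      # before subsetting: `[.data.frame`
  cells <- as.matrix(df[, -1L, drop = FALSE])  # would de-duplicate names
  colnames(cells) <- expIds
  cells[cells == ""] <- "0"
  bad <- which(array(!(cells %in% c("0", "1")), dim(cells)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-binary cell value %s at row %s (unit %s), column %s",
      dQuote(cells[bad[1L, 1L], bad[1L, 2L]]), bad[1L, 1L],
      ids[bad[1L, 1L]], dQuote(colnames(cells)[bad[1L, 2L]])))
  }
  if (anyDuplicated(ids))
    stop("duplicate unit ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(cells)))
    stop("duplicate experiment ids: ",
         paste(unique(colnames(cells)[duplicated(colnames(cells))]),
               collapse = ", "))
  mode(cells) <- "integer"
  rownames(cells) <- ids
  DetectionMatrix(cells, unitLevel = unitLevel)
}

#' Write a detection matrix to CSV
#'
#' Inverse of [readDetectionMatrix()]; preserves unit and experiment order
#' so that the round trip is the identity.
#'
#' @param x a [DetectionMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDetectionMatrix <- function(x, path) {
  df <- data.frame(unit_id = unitIds(x), detections(x),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse a site-level matrix to protein level
#'
#' A protein is credited to an experiment as soon as at least one of its
#' sites is detected there (the union rule).  Site ids must follow the
#' `<protein>_<residue><position>` convention; everything before the last
#' underscore is the protein id.
#'
#' @param x a site-level [DetectionMatrix-class].
#' @return a protein-level [DetectionMatrix-class] with the same
#'   experiments.
#' @export
collapseToProteins <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  if (unitLevel(x) != "site")
    stop("collapseToProteins expects a site-level matrix")
  ids <- unitIds(x)
  ok <- grepl("^.+_[STY][0-9]+$", ids)
  if (!all(ok))
    stop("unit ids without a parsable protein prefix: ",
         paste(head(ids[!ok], 5L), collapse = ", "))
  prot <- sub("_[STY][0-9]+$", "", ids)
  agg <- rowsum(detections(x), group = prot, reorder = FALSE)
  agg <- (agg > 0L) + 0L
  DetectionMatrix(agg, unitLevel = "protein")
}

#' Keep units detected in at least k experiments
#'
#' The high-confidence restriction used throughout the analyses ("3X" when
#' `k = 3`): a unit survives iff its row sum is at least `k`.  The
#' experiment set is unchanged; the result may be empty.
#'
#' @param x a [DetectionMatrix-class].
#' @param k minimum number of detecting experiments (`k >= 1`).
#' @return the filtered [DetectionMatrix-class].
#' @export
filterMinExperiments <- function(x, k) {
  stopifnot(is(x, "DetectionMatrix"), k >= 1)
  keep <- rowSums(detections(x)) >= k
  DetectionMatrix(detections(x)[keep, , drop = FALSE],
                  unitLevel = unitLevel(x))
}

#' Merge all experiments into one non-redundant column
#'
#' Produces the single-column compendium used in the two-list analyses: a
#' unit is detected in the merged experiment iff it was detected anywhere.
#' The unit set is unchanged, so the merged column sum equals the
#' non-redundant unit count.
#'
#' @param x a [DetectionMatrix-class].
#' @param label id of the merged pseudo-experiment.
#' @return a single-column [DetectionMatrix-class].
#' @export
mergeExperiments <- function(x, label = "merged") {
  stopifnot(is(x, "DetectionMatrix"))
  merged <- matrix((rowSums(detections(x)) > 0L) + 0L, ncol = 1L,
                   dimnames = list(unitIds(x), label))
  DetectionMatrix(merged, unitLevel = unitLevel(x))
}

#' Pairwise Jaccard similarity between experiments
#'
#' Overlap QC: highly similar experiments would artificially inflate the
#' apparent saturation, so the Jaccard similarity |A∩B| / |A∪B| of the
#' detected-unit sets is computed for every pair of experiments and
#' summarized by its mean and maximum.  An empty experiment has similarity
#' 0 against any non-empty one; two empty experiments are undefined and
#' raise an error.
#'
#' @param x a [DetectionMatrix-class] with at least two experiments.
#' @return a [JaccardSummary-class].
#' @export
jaccardQC <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  if (ncol(x) < 2L) stop("jaccardQC needs at least two experiments")
  m <- detections(x)
  inter <- crossprod(m)                       # |A_i ∩ A_j|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter     # |A_i ∪ A_j|
  if (any(uni == 0 & upper.tri(uni)))
    stop("two experiments with no detections: Jaccard undefined")
  sim <- ifelse(uni == 0, 1, inter / uni)     # only diagonal can have uni=0
  diag(sim) <- 1
  off <- sim[upper.tri(sim)]
  new("JaccardSummary", similarity = sim,
      meanSimilarity = mean(off), maxSimilarity = max(off))
}

setMethod("show", "JaccardSummary", function(object) {
  cat("JaccardSummary over", nrow(object@similarity), "experiments\n")
  cat(sprintf("  mean off-diagonal similarity: %.3f\n",
              object@meanSimilarity))
  cat(sprintf("  max  off-diagonal similarity: %.3f\n",
              object@maxSimilarity))
})
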