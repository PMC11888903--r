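#' @useDynLib phca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' PointCloud: a finite set of points in Euclidean space
#'
#' A thin container for an \eqn{n \times m} coordinate matrix under the
#' Euclidean metric. Clouds may be empty or contain a single point; these
#' degenerate cases are legal throughout the package (per-class clouds of a
#' classifier must never fail to build).
#'
#' @slot coordinates numeric matrix, one point per row; all entries finite.
#' @export
setClass("PointCloud", representation(coordinates = "matrix"))

setValidity("PointCloud", function(object) {
  x <- object@coordinates
  if (!is.numeric(x)) return("coordinates must be a numeric matrix")
  if (length(x) && !all(is.finite(x))) return("coordinates must be finite")
  TRUE
})

#' Construct a PointCloud
#'
#' @param coordinates numeric matrix (points in rows) or a numeric vector,
#'   interpreted as a single m-dimensional point.
#' @return A [PointCloud-class] object.
#' @examples
#' PointCloud(rbind(c(0, 0), c(3, 4)))
#' @export
PointCloud <- function(coordinates) {
  if (is.null(dim(coordinates))) coordinates <- matrix(coordinates, nrow = 1)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  new("PointCloud", coordinates = coordinates)
}

#' Parameters of a Vietoris-Rips filtration
#'
#' The filtration is parameterised by a radius \eqn{\epsilon}: two points are
#' connected once their distance is at most \eqn{2\epsilon}. `maxScale` is the
#' filtration horizon in the same radius units; `NA` means "auto", i.e. half
#' the maximum pairwise distance of the cloud being filtered. Homology is
#' available in dimensions 0 (components) and 1 (loops); dimension 2 is not
#' supported.
#'
#' @slot maxDimension integer, 0 or 1.
#' @slot maxScale numeric; nonnegative horizon, or `NA_real_` for auto.
#' @export
setClass("FiltrationParams",
         representation(maxDimension = "integer", maxScale = "numeric"))

setValidity("FiltrationParams", function(object) {
  d <- object@maxDimension
  if (length(d) != 1L || is.na(d) || d < 0L)
    return("maxDimension must be a single nonnegative integer")
  if (d > 1L) return("homology dimension > 1 is unsupported")
  s <- object@maxScale
  if (length(s) != 1L) return("maxScale must be a single value")
  if (!is.na(s) && (!is.finite(s) || s < 0))
    return("explicit maxScale must be finite and >= 0")
  TRUE
})

#' Construct FiltrationParams
#'
#' @param maxDimension highest homology dimension to compute (0 or 1).
#' @param maxScale filtration horizon in radius units, or `"auto"`/`NA` for
#'   half the maximum pairwise distance (the usual convention).
#' @return A [FiltrationParams-class] object.
#' @export
FiltrationParams <- function(maxDimension = 1L, maxScale = NA_real_) {
  if (identical(maxScale, "auto")) maxScale <- NA_real_
  if (length(maxDimension) == 1L && !is.na(maxDimension) && maxDimension > 1)
    stop("homology dimension > 1 is unsupported")
  new("FiltrationParams", maxDimension = as.integer(maxDimension),
      maxScale = as.numeric(maxScale))
}

#' Persistence diagram
#'
#' The (dimension, birth, death) summary of a Vietoris-Rips filtration,
#' stored as a data frame plus a `capped` flag per row marking classes that
#' were still alive at the filtration horizon and whose death was therefore
#' truncated at `sourceMaxScale`. Births and deaths are radius units.
#'
#' @slot rows data.frame with columns `dim` (integer), `birth`, `death`
#'   (numeric) and `capped` (logical).
#' @slot sourceMaxScale numeric, the horizon of the producing filtration.
#' @export
setClass("PersistenceDiagram",
         representation(rows = "data.frame", sourceMaxScale = "numeric"))

setValidity("PersistenceDiagram", function(object) {
  r <- object@rows
  need <- c("dim", "birth", "death", "capped")
  if (!all(need %in% names(r))) return("rows must have dim,birth,death,capped")
  if (nrow(r)) {
    tol <- 1e-9 * max(1, object@sourceMaxScale)
    if (any(r$birth < -tol)) return("births must be nonnegative")
    if (any(r$death < r$birth - tol)) return("death must be >= birth")
    if (any(r$death > object@sourceMaxScale + tol))
      return("death must be <= sourceMaxScale")
  }
  TRUE
})

# canonical row order makes diagrams comparable as tables
.makeDiagram <- function(dim, birth, death, capped, maxScale) {
  rows <- data.frame(dim = as.integer(dim), birth = as.numeric(birth),
                     death = as.numeric(death), capped = as.logical(capped))
  rows <- rows[order(rows$dim, rows$birth, rows$death, rows$capped), ,
               drop = FALSE]
  rownames(rows) <- NULL
  new("PersistenceDiagram", rows = rows, sourceMaxScale = as.numeric(maxScale))
}

#' PHCA model
#'
#' Fitted state of the Persistent Homology Classification Algorithm: the
#' training cloud of every class together with its cached baseline total
#' lifespan over the active homology dimensions. Prediction scores a query
#' against class \eqn{i} as the absolute change in total lifespan when the
#' query is inserted into cloud \eqn{X_i}.
#'
#' @slot classLabels character, the classes in training-declared order (the
#'   tie-break order at prediction time).
#' @slot classClouds named list of coordinate matrices, one per class.
#' @slot baselineTotals named numeric, total lifespan of each class diagram.
#' @slot dims integer vector of active homology dimensions: 0, 1 or c(0, 1).
#' @export
setClass("PHCAModel",
         representation(classLabels = "character", classClouds = "list",
                        baselineTotals = "numeric", dims = "integer"))

setValidity("PHCAModel", function(object) {
  k <- length(object@classLabels)
  if (k < 1L) return("model needs at least one class")
  if (anyDuplicated(object@classLabels)) return("class labels must be distinct")
  if (length(object@classClouds) != k || length(object@baselineTotals) != k)
    return("clouds and baseline totals must match classLabels")
  if (any(vapply(object@classClouds, nrow, 0L) < 1L))
    return("every class needs at least one training point")
  if (!all(object@dims %in% 0:1) || !length(object@dims))
    return("dims must be a nonempty subset of {0, 1}")
  TRUE
})

#' Labelled feature dataset
#'
#' A feature matrix with one class label per row and an ordered class
#' catalogue. The catalogue order is the canonical class order used for
#' confusion matrices, tie-breaks and reports.
#'
#' @slot features numeric matrix, n x m, no missing values.
#' @slot labels character vector of length n; every value is in the catalogue.
#' @slot catalogue character, ordered distinct class labels.
#' @slot ids character row identifiers.
#' @export
setClass("LabelledDataset",
         representation(features = "matrix", labels = "character",
                        catalogue = "character", ids = "character"))

setValidity("LabelledDataset", function(object) {
  n <- nrow(object@features)
  if (n < 1L) return("dataset must have at least one row")
  if (!all(is.finite(object@features))) return("features must be finite")
  if (length(object@labels) != n || length(object@ids) != n)
    return("labels and ids must match feature rows")
  if (anyDuplicated(object@catalogue)) return("catalogue must be distinct")
  if (!all(object@labels %in% object@catalogue))
    return("every label must appear in the catalogue")
  TRUE
})

#' Construct a LabelledDataset
#'
#' @param features numeric matrix or data.frame of features (rows = items).
#' @param labels class label per row (coerced to character).
#' @param catalogue ordered class catalogue; defaults to the sorted distinct
#'   labels.
#' @param ids row identifiers; defaults to `"r1", "r2", ...`.
#' @return A [LabelledDataset-class].
#' @export
LabelledDataset <- function(features, labels, catalogue = NULL, ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  if (is.null(catalogue)) catalogue <- sort(unique(labels))
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(features)))
  new("LabelledDataset", features = features, labels = labels,
      catalogue = as.character(catalogue), ids = as.character(ids))
}

#' Classification metrics report
#'
#' Per-class one-vs-rest confusion counts, macro-averaged precision, recall,
#' F1 and specificity, overall accuracy, and the full confusion matrix
#' (rows = true class, columns = predicted class, catalogue order).
#'
#' @slot perClass data.frame with columns class, TP, FP, FN, TN, precision,
#'   recall, f1, specificity.
#' @slot macro named numeric: precision, recall, f1, specificity.
#' @slot accuracy numeric scalar between 0 and 1.
#' @slot confusion integer matrix a_ij = count of true class i predicted j.
#' @export
setClass("MetricsReport",
         representation(perClass = "data.frame", macro = "numeric",
                        accuracy = "numeric", confusion = "matrix"))

setValidity("MetricsReport", function(object) {
  m <- object@macro
  if (!all(c("precision", "recall", "f1", "specificity") %in% names(m)))
    return("macro must name precision, recall, f1, specificity")
  vals <- c(m, object@accuracy)
  if (any(vals < -1e-12 | vals > 1 + 1e-12)) return("metrics must be in [0,1]")
  TRUE
})
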