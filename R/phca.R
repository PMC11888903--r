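# The Persistent Homology Classification Algorithm. Training computes the
# persistence of each class cloud X_i and caches its total lifespan; a query
# alpha is scored against class i as
#   Score(X_i) = | sum of lifespans of P(X_i u {alpha}) - sum for P(X_i) |
# and assigned to the argmin class. The filtration horizon of the augmented
# cloud is recomputed from the augmented cloud itself (half its diameter).

.dimsFromChoice <- function(choice) {
  switch(choice,
         H0_ONLY = 0L,
         H1_ONLY = 1L,
         H0_AND_H1 = c(0L, 1L),
         stop("unknown homology dimension choice: ", choice))
}

#' Homology dimension choices for PHCA
#'
#' The tuning space of the classifier: score on components only
#' (`"H0_ONLY"`), loops only (`"H1_ONLY"`), or both (`"H0_AND_H1"`).
#'
#' @return character vector of the three choices.
#' @export
homologyDimensionChoices <- function() c("H0_ONLY", "H1_ONLY", "H0_AND_H1")

.phcaTotal <- function(x, dims) {
  if (identical(dims, 0L)) return(.h0TotalLifespan(x))
  diag <- vrPersistence(x, FiltrationParams(maxDimension = max(dims)))
  totalLifespan(diag, dims)
}

#' Fit a PHCA model
#'
#' Splits the training data by class and caches, per class, the coordinate
#' cloud and its baseline total persistence lifespan over the active
#' homology dimensions. Fitting is deterministic. With dimension 0 only the
#' totals use the minimum-spanning-tree closed form; otherwise the full
#' Vietoris-Rips engine runs per class.
#'
#' @param x numeric feature matrix (rows = training points) or a
#'   [LabelledDataset-class] (in which case `labels` is ignored).
#' @param labels class label per row.
#' @param choice one of [homologyDimensionChoices()]; default `"H0_ONLY"`,
#'   the configuration that wins validation in practice.
#' @param catalogue ordered class catalogue; defaults to order of first
#'   appearance in `labels`. Every catalogue class must have at least one row.
#' @return A [PHCAModel-class].
#' @examples
#' m <- phcaFit(matrix(c(0, 3, 10, 13), ncol = 1), c("A", "A", "B", "B"))
#' predictOne(m, 1.4) # "A"
#' @export
phcaFit <- function(x, labels = NULL, choice = "H0_ONLY", catalogue = NULL) {
  if (is(x, "LabelledDataset")) {
    labels <- x@labels
    if (is.null(catalogue)) catalogue <- x@catalogue
    x <- x@features
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("training features must be finite")
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(catalogue)) catalogue <- unique(labels)
  dims <- .dimsFromChoice(match.arg(choice, homologyDimensionChoices()))

  clouds <- lapply(catalogue, function(cl) {
    idx <- which(labels == cl)
    if (!length(idx)) stop("class '", cl, "' has no training rows")
    x[idx, , drop = FALSE]
  })
  names(clouds) <- catalogue
  totals <- vapply(clouds, .phcaTotal, 0, dims = dims)
  new("PHCAModel", classLabels = as.character(catalogue), classClouds = clouds,
      baselineTotals = totals, dims = dims)
}

#' @describeIn scoreClass The absolute change in total persistence lifespan of the class cloud when
#' the query is inserted: `|L(X_i u {q}) - L(X_i)|`, each total taken over
#' the model's active homology dimensions, the augmented cloud filtered up
#' to half its own diameter. A query identical to a training point of the
#' class scores exactly 0.
#'
#' @param model a [PHCAModel-class].
#' @param label a class label present in the model.
#' @param query numeric vector matching the training feature dimension.
#' @return Nonnegative numeric scalar.
#' @export
setMethod("scoreClass", "PHCAModel", function(model, label, query) {
  label <- as.character(label)
  if (!label %in% model@classLabels) stop("unknown class label: ", label)
  cloud <- model@classClouds[[label]]
  query <- as.numeric(query)
  if (length(query) != ncol(cloud))
    stop("query dimension ", length(query), " does not match training ",
         "dimension ", ncol(cloud))
  if (!all(is.finite(query))) stop("query coordinates must be finite")
  y <- rbind(cloud, query)
  abs(.phcaTotal(y, model@dims) - model@baselineTotals[[label]])
})

#' Classify a single query point
#'
#' Scores the query against every class and returns the label minimising the
#' score; ties are broken by position in the model's class order (first
#' wins).
#'
#' @param model a [PHCAModel-class].
#' @param query numeric vector.
#' @return A class label (character scalar).
#' @export
setMethod("predictOne", "PHCAModel", function(model, query) {
  scores <- vapply(model@classLabels, function(cl)
    scoreClass(model, cl, query), 0)
  model@classLabels[[which.min(scores)]]
})

#' Classify a table of query points
#'
#' Row-wise [predictOne()]; rows are independent and output order follows
#' input order.
#'
#' @param object a [PHCAModel-class].
#' @param newdata numeric matrix (queries in rows), data.frame, or a
#'   [LabelledDataset-class].
#' @return Character vector of predicted labels.
#' @export
setMethod("predict", "PHCAModel", function(object, newdata) {
  if (is(newdata, "LabelledDataset")) newdata <- newdata@features
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(character())
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    out[i] <- tryCatch(predictOne(object, newdata[i, ]),
                       error = function(e)
                         stop("prediction failed at row ", i, ": ",
                              conditionMessage(e)))
  }
  out
})

#' @rdname classCatalogue
#' @export
setMethod("classCatalogue", "PHCAModel", function(x) x@classLabels)

#' Persist / restore a PHCA model
#'
#' Writes a JSON sidecar (class labels, homology dimensions, baseline
#' totals) plus one coordinate CSV per class into `dir`.
#'
#' @param model a [PHCAModel-class].
#' @param dir directory to create/use.
#' @return `saveModel` returns `dir` invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(classLabels = model@classLabels, dims = model@dims,
               baselineTotals = as.list(model@baselineTotals),
               cloudFiles = as.list(sprintf("class_%03d.csv",
                                            seq_along(model@classLabels))))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = FALSE, digits = NA)
  for (i in seq_along(model@classLabels)) {
    cl <- model@classClouds[[i]]
    lines <- c(paste(sprintf("f%d", seq_len(ncol(cl)) - 1L), collapse = ","),
               apply(cl, 1L, function(r)
                 paste(sprintf("%.17g", r), collapse = ",")))
    writeLines(lines, file.path(dir, meta$cloudFiles[[i]]))
  }
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  clouds <- lapply(meta$cloudFiles, function(f)
    as.matrix(utils::read.csv(file.path(dir, f))))
  names(clouds) <- meta$classLabels
  totals <- unlist(meta$baselineTotals)[meta$classLabels]
  new("PHCAModel", classLabels = meta$classLabels, classClouds = clouds,
      baselineTotals = totals, dims = as.integer(meta$dims))
}

setMethod("show", "PHCAModel", function(object) {
  cat(sprintf("PHCAModel: %d classes, homology dims {%s}\n",
              length(object@classLabels),
              paste(object@dims, collapse = ",")))
  sizes <- vapply(object@classClouds, nrow, 0L)
  cat(sprintf("  class sizes %d-%d, baseline totals %.4g-%.4g\n",
              min(sizes), max(sizes), min(object@baselineTotals),
              max(object@baselineTotals)))
  invisible(NULL)
})
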