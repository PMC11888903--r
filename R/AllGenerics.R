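#' Filtration horizon of a point cloud
#'
#' Half the maximum pairwise Euclidean distance of the cloud: the scale at
#' which every pair of points is connected in the Vietoris-Rips filtration
#' under the radius convention (join when \eqn{d \le 2\epsilon}). Returns 0
#' for clouds with fewer than two points.
#'
#' @param cloud a [PointCloud-class] or a numeric coordinate matrix.
#' @return Nonnegative numeric scalar, in radius units.
#' @examples
#' maxScale(PointCloud(rbind(c(0, 0), c(3, 4)))) # 2.5
#' @export
setGeneric("maxScale", function(cloud) standardGeneric("maxScale"))

#' Total lifespan of a persistence diagram
#'
#' Sum of death - birth over the rows whose homology dimension lies in
#' `dims`. Rows capped at the filtration horizon contribute their truncated
#' lifespan; zero-lifespan rows contribute nothing.
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param dims integer vector of homology dimensions to include.
#' @return Nonnegative numeric scalar.
#' @export
setGeneric("totalLifespan",
           function(diagram, dims = 0L) standardGeneric("totalLifespan"))

#' Score a query point against one class
#'
#' Generic for the class-wise score of the persistent-homology classifier;
#' see the [PHCAModel-class] method.
#'
#' @param model a fitted classifier.
#' @param label a class label present in the model.
#' @param query numeric vector matching the training feature dimension.
#' @return Nonnegative numeric scalar.
#' @export
setGeneric("scoreClass",
           function(model, label, query) standardGeneric("scoreClass"))

#' Classify a single query point
#'
#' Generic for single-query prediction; see the [PHCAModel-class] method.
#'
#' @param model a fitted classifier.
#' @param query numeric vector.
#' @return A class label (character scalar).
#' @export
setGeneric("predictOne", function(model, query) standardGeneric("predictOne"))

#' Number of items in a dataset
#' @param x a [LabelledDataset-class].
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Class label accessor
#' @param x a [LabelledDataset-class].
#' @return character vector of per-row labels.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Class catalogue accessor
#' @param x a [LabelledDataset-class] or [PHCAModel-class].
#' @return character vector of ordered distinct class labels.
#' @export
setGeneric("classCatalogue", function(x) standardGeneric("classCatalogue"))

#' Feature matrix accessor
#' @param x a [LabelledDataset-class].
#' @return numeric matrix.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Diagram rows accessor
#' @param diagram a [PersistenceDiagram-class].
#' @return data.frame with columns dim, birth, death, capped.
#' @export
setGeneric("diagramRows", function(diagram) standardGeneric("diagramRows"))
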