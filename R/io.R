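# Dataset I/O and the landmark front-end port. Feature tables travel as CSV
# with header id,label,<feature columns> ('.' decimal, UTF-8), floats
# printed with 17 significant digits so round trips are lossless. The
# image-to-landmark extractor sits behind a single-function port (option
# "phca.landmarkBackend"); everything else in the package works with the
# port absent.

#' Write / read a labelled feature table as CSV
#'
#' Header `id,label,<features>`; the canonical landmark dialect names the 63
#' columns `x0,y0,z0,...,x20,y20,z20` but any feature width round-trips.
#'
#' @param data a [LabelledDataset-class].
#' @param path file path.
#' @return `writeLandmarkCsv`: `path` invisibly. `readLandmarkCsv`: a
#'   [LabelledDataset-class] (catalogue = order of first appearance).
#' @export
writeLandmarkCsv <- function(data, path) {
  stopifnot(is(data, "LabelledDataset"))
  x <- data@features
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("f", seq_len(ncol(x)) - 1L)
  header <- paste(c("id", "label", cols), collapse = ",")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(data@ids[i], data@labels[i], sprintf("%.17g", x[i, ])),
          collapse = ","), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeLandmarkCsv
#' @export
readLandmarkCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("feature CSV must have 'id' and 'label' columns: ", path)
  featCols <- setdiff(names(df), c("id", "label"))
  x <- as.matrix(df[featCols])
  storage.mode(x) <- "double"
  LabelledDataset(x, df$label, catalogue = unique(as.character(df$label)),
                  ids = as.character(df$id))
}

#' Read a point cloud from CSV
#'
#' Plain numeric CSV with a header row; every column is a coordinate.
#'
#' @param path file path.
#' @return A [PointCloud-class].
#' @export
readCloudCsv <- function(path) {
  PointCloud(as.matrix(utils::read.csv(path)))
}

#' Extract hand landmarks from one image (front-end port)
#'
#' The image-to-landmark model (a palm detector plus a hand-landmark
#' localiser producing 21 three-dimensional knuckle coordinates, x and y in
#' normalised image coordinates and z the relative depth) is an optional
#' external dependency behind this single-function port. A backend is a
#' function taking an image path and returning either
#' `list(converted = TRUE, coords = <numeric 63-vector>)` (first detected
#' hand) or `list(converted = FALSE)` when no hand is found.
#'
#' @param imagePath path to a JPEG/PNG image.
#' @param backend backend function; defaults to
#'   `getOption("phca.landmarkBackend")`. An error is raised when no
#'   backend is configured.
#' @return list with `imageId`, `converted`, and (when converted) `coords`.
#' @export
extractLandmarks <- function(imagePath,
                             backend = getOption("phca.landmarkBackend")) {
  if (is.null(backend))
    stop("no landmark backend configured; install/register one via ",
         "options(phca.landmarkBackend = <function>)")
  if (!file.exists(imagePath)) stop("image not found: ", imagePath)
  res <- backend(imagePath)
  if (!is.list(res) || is.null(res$converted))
    stop("backend must return list(converted=, coords=)")
  if (isTRUE(res$converted)) {
    coords <- as.numeric(res$coords)
    if (length(coords) != 63L || !all(is.finite(coords)))
      stop("backend returned malformed coordinates for ", imagePath)
    list(imageId = basename(imagePath), converted = TRUE, coords = coords)
  } else {
    list(imageId = basename(imagePath), converted = FALSE)
  }
}

#' Extract landmarks for a class-per-subdirectory image tree
#'
#' Walks `imageDir/<class>/<files>` in lexicographic order, runs
#' [extractLandmarks()] on every image, and assembles the converted records
#' into a dataset plus a per-class conversion report. Classes whose images
#' all fail conversion (or that contain no images) are reported with zero
#' converted and excluded from the dataset.
#'
#' @param imageDir directory with one subdirectory per class.
#' @param backend landmark backend function (see [extractLandmarks()]).
#' @return list with `dataset` ([LabelledDataset-class]) and `report`
#'   (data.frame: class, converted, notConverted).
#' @export
batchExtract <- function(imageDir,
                         backend = getOption("phca.landmarkBackend")) {
  classes <- sort(list.dirs(imageDir, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories in ", imageDir)
  feats <- list(); labs <- character(); ids <- character()
  report <- data.frame(class = classes, converted = 0L, notConverted = 0L)
  for (ci in seq_along(classes)) {
    files <- sort(list.files(file.path(imageDir, classes[ci]),
                             full.names = TRUE))
    for (f in files) {
      rec <- extractLandmarks(f, backend = backend)
      if (rec$converted) {
        feats[[length(feats) + 1L]] <- rec$coords
        labs <- c(labs, classes[ci])
        ids <- c(ids, paste0(classes[ci], "/", rec$imageId))
        report$converted[ci] <- report$converted[ci] + 1L
      } else {
        report$notConverted[ci] <- report$notConverted[ci] + 1L
      }
    }
  }
  if (!length(feats)) stop("no image was converted under ", imageDir)
  x <- do.call(rbind, feats)
  colnames(x) <- paste0(rep(c("x", "y", "z"), 21L), rep(0:20, each = 3L))
  keptClasses <- classes[classes %in% unique(labs)]
  list(dataset = LabelledDataset(x, labs, catalogue = keptClasses, ids = ids),
       report = report)
}

#' Read an experiment configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) with the fields understood by
#' [runTrials()] and the CLI: `dataset` (either `path` to a feature CSV or
#' `synthetic` with a generator spec), `roster`, `n_trials`,
#' `test_fraction`, `n_iter`, `folds`, `base_seed`, `balance`, `alpha`.
#'
#' @param path configuration file path.
#' @return Named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else stop("unsupported config format: ", path)
}

# resolve the dataset declared in a config into a LabelledDataset
.configDataset <- function(cfg, seed) {
  ds <- cfg$dataset
  if (!is.null(ds$path)) return(readLandmarkCsv(ds$path))
  sp <- ds$synthetic
  if (is.null(sp)) stop("config dataset needs 'path' or 'synthetic'")
  type <- if (is.null(sp$type)) "hand" else sp$type
  sd <- if (is.null(sp$seed)) seed else sp$seed
  if (type == "hand") {
    makeHandLike(k = if (is.null(sp$k)) 4L else sp$k,
                 classSize = if (is.null(sp$class_size)) 50L else
                   sp$class_size,
                 jitterSd = if (is.null(sp$jitter_sd)) 0.01 else sp$jitter_sd,
                 rho = if (is.null(sp$rho)) 0 else sp$rho,
                 seed = sd)$dataset
  } else if (type == "blobs") {
    makeGaussianClasses(k = if (is.null(sp$k)) 3L else sp$k,
                        sizes = if (is.null(sp$class_size)) 50L else
                          sp$class_size,
                        m = if (is.null(sp$m)) 63L else sp$m,
                        separation = if (is.null(sp$separation)) 10 else
                          sp$separation,
                        withinSd = if (is.null(sp$within_sd)) 1 else
                          sp$within_sd,
                        seed = sd)
  } else stop("unknown synthetic dataset type: ", type)
}
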