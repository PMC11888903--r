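# Experiment harness: stratified 90-10 splitting, standard scaling fit on
# training data only, one-vs-rest confusion metrics with macro averaging,
# and misclassification ranking.

#' @rdname nSamples
#' @export
setMethod("nSamples", "LabelledDataset", function(x) nrow(x@features))

#' @rdname classLabels
#' @export
setMethod("classLabels", "LabelledDataset", function(x) x@labels)

#' @rdname classCatalogue
#' @export
setMethod("classCatalogue", "LabelledDataset", function(x) x@catalogue)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "LabelledDataset", function(x) x@features)

setMethod("show", "LabelledDataset", function(object) {
  cat(sprintf("LabelledDataset: %d rows x %d features, %d classes\n",
              nrow(object@features), ncol(object@features),
              length(object@catalogue)))
  invisible(NULL)
})

.subsetDataset <- function(data, idx) {
  new("LabelledDataset", features = data@features[idx, , drop = FALSE],
      labels = data@labels[idx], catalogue = data@catalogue,
      ids = data@ids[idx])
}

# canonical within-class row order (lexicographic over features, then id),
# so seeded subsampling partitions the row *multiset* independently of the
# storage order of the table
.canonicalClassOrder <- function(data, cl) {
  idx <- which(data@labels == cl)
  key <- as.data.frame(data@features[idx, , drop = FALSE])
  key$..id <- data@ids[idx]
  idx[do.call(order, key)]
}

#' Stratified train/test split
#'
#' Splits each class separately so class proportions carry over to the test
#' set. Per-class test counts follow the exact quotas `count * fraction`
#' with largest-remainder rounding, so the total test size is exactly the
#' rounded fraction of the data even for imbalanced classes. Reproducible
#' per seed, and invariant to the row order of the input (the same seed
#' partitions the same row multiset identically).
#'
#' @param data a [LabelledDataset-class]; every class needs >= 2 rows.
#' @param testFraction fraction of rows held out, in (0, 1); default 0.1.
#' @param seed integer seed.
#' @return list with elements `train`, `test` (both [LabelledDataset-class])
#'   and `testIdx` (integer row indices of the test items).
#' @export
stratifiedSplit <- function(data, testFraction = 0.1, seed = 1L) {
  stopifnot(is(data, "LabelledDataset"),
            testFraction > 0, testFraction < 1)
  counts <- table(factor(data@labels, levels = data@catalogue))
  if (any(counts < 2L))
    stop("every class needs at least 2 rows to split; offending class: ",
         names(counts)[which(counts < 2L)[1L]])

  quota <- as.numeric(counts) * testFraction
  take <- floor(quota)
  total <- floor(sum(quota) + 0.5)
  short <- total - sum(take)
  if (short > 0) {
    frac <- quota - take
    extra <- order(-frac, seq_along(frac))[seq_len(short)]
    take[extra] <- take[extra] + 1L
  }
  take <- pmin(take, as.numeric(counts) - 1L) # never empty a training class

  testIdx <- integer()
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(data@catalogue)) {
      pool <- .canonicalClassOrder(data, data@catalogue[ci])
      if (take[ci] > 0)
        testIdx <- c(testIdx, sample(pool, take[ci]))
    }
  })
  testIdx <- sort(testIdx)
  list(train = .subsetDataset(data, setdiff(seq_len(nrow(data@features)),
                                            testIdx)),
       test = .subsetDataset(data, testIdx),
       testIdx = testIdx)
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently and deals its rows across the `k` folds
#' round-robin, so every fold holds (up to rounding) the same class mix.
#'
#' @param labels character vector of class labels.
#' @param k number of folds; every class must have at least `k` rows.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1:k`, one per row.
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least ", k, " rows for ", k,
         "-fold CV; offending class: ", names(counts)[which(counts < k)[1L]])
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Standard scaler (fit on training data only)
#'
#' Estimates per-feature mean and population standard deviation (divisor n)
#' on the training data; `applyScaler` centres and rescales any dataset
#' with those statistics, so the test transformation never sees test data.
#' Features with zero standard deviation are centred but not divided.
#'
#' @param train a [LabelledDataset-class] or numeric matrix.
#' @return `fitScaler`: list with `mean` and `sd` vectors (class
#'   `phcaScaler`). `applyScaler`: object of the same type as `data`.
#' @export
fitScaler <- function(train) {
  x <- if (is(train, "LabelledDataset")) train@features else as.matrix(train)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  structure(list(mean = mu, sd = sdv), class = "phcaScaler")
}

#' @rdname fitScaler
#' @param params a scaler returned by `fitScaler`.
#' @param data dataset or matrix to transform.
#' @export
applyScaler <- function(params, data) {
  stopifnot(inherits(params, "phcaScaler"))
  x <- if (is(data, "LabelledDataset")) data@features else as.matrix(data)
  div <- ifelse(params$sd == 0, 1, params$sd)
  x <- sweep(sweep(x, 2L, params$mean, "-"), 2L, div, "/")
  if (is(data, "LabelledDataset")) {
    data@features <- x
    data
  } else x
}

#' Classification metrics from predictions
#'
#' Builds the confusion matrix `a_ij` (true class i, predicted j, catalogue
#' order) and the one-vs-rest counts per class, then
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R), specificity = TN/(TN+FP), each macro-averaged
#' (unweighted) over classes, and accuracy = correct/total over the whole
#' test set. A class with undefined precision or recall contributes 0 for
#' the undefined quantity and for its F1.
#'
#' @param truth true labels.
#' @param predicted predicted labels, same length.
#' @param catalogue ordered class catalogue; defaults to sorted distinct
#'   values of `truth` and `predicted`.
#' @return A [MetricsReport-class].
#' @export
evaluateMetrics <- function(truth, predicted, catalogue = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!length(truth)) stop("cannot evaluate zero predictions")
  if (is.null(catalogue)) catalogue <- sort(unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% catalogue))
    stop("labels outside the catalogue")

  conf <- table(factor(truth, levels = catalogue),
                factor(predicted, levels = catalogue))
  conf <- matrix(as.integer(conf), nrow = length(catalogue),
                 dimnames = list(true = catalogue, predicted = catalogue))
  n <- sum(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- n - tp - fp - fn

  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  prec <- safe(tp, tp + fp)
  rec <- safe(tp, tp + fn)
  f1 <- ifelse(tp + fp == 0 | tp + fn == 0, 0,
               safe(2 * prec * rec, prec + rec))
  spec <- safe(tn, tn + fp)

  perClass <- data.frame(class = catalogue, TP = tp, FP = fp, FN = fn,
                         TN = tn, precision = prec, recall = rec, f1 = f1,
                         specificity = spec, row.names = NULL)
  new("MetricsReport", perClass = perClass,
      macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                specificity = mean(spec)),
      accuracy = sum(tp) / n, confusion = conf)
}

#' Flat metric vector of a report
#'
#' The five headline metrics in canonical order: macro precision, recall,
#' F1, specificity, then overall accuracy.
#'
#' @param report a [MetricsReport-class].
#' @return Named numeric vector of length 5.
#' @export
metricVector <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  c(report@macro[c("precision", "recall", "f1", "specificity")],
    accuracy = report@accuracy)
}

#' Ranked misclassification report
#'
#' Off-diagonal confusion cells sorted by descending count; ties broken by
#' catalogue order of (true, predicted). Per-trial confusion matrices may be
#' summed element-wise before calling, which yields the cumulative report.
#'
#' @param x a [MetricsReport-class] or a confusion matrix (true in rows).
#' @return data.frame with columns `true`, `predicted`, `count` (possibly
#'   zero rows).
#' @export
misclassificationReport <- function(x) {
  conf <- if (is(x, "MetricsReport")) x@confusion else as.matrix(x)
  cats <- rownames(conf)
  out <- data.frame(true = character(), predicted = character(),
                    count = integer())
  for (i in seq_len(nrow(conf)))
    for (j in seq_len(ncol(conf)))
      if (i != j && conf[i, j] > 0)
        out <- rbind(out, data.frame(true = cats[i], predicted = cats[j],
                                     count = as.integer(conf[i, j])))
  if (nrow(out))
    out <- out[order(-out$count, match(out$true, cats),
                     match(out$predicted, cats)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport: accuracy %.4f | macro P %.4f R %.4f ",
                     "F1 %.4f Spec %.4f (%d classes, n=%d)\n"),
              object@accuracy, object@macro[["precision"]],
              object@macro[["recall"]], object@macro[["f1"]],
              object@macro[["specificity"]], nrow(object@perClass),
              sum(object@confusion)))
  invisible(NULL)
})
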