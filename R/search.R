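# Random-search hyperparameter tuning with stratified k-fold
# cross-validation, and the multi-trial experiment driver: per trial, a
# fresh stratified 90-10 split, a 20-draw random search per classifier with
# 5-fold CV (scaler refit inside each fold on the training folds only),
# refit on the full training set with the winning combination, and
# evaluation on the held-out test set.

.comboKey <- function(params)
  paste(names(params), vapply(params, function(v)
    paste(format(v, digits = 17), collapse = "|"), ""), sep = "=",
    collapse = ";")

.cvAccuracy <- function(entry, train, params, foldId, seed) {
  folds <- sort(unique(foldId))
  acc <- numeric(length(folds))
  for (f in folds) {
    trIdx <- which(foldId != f)
    vaIdx <- which(foldId == f)
    tr <- .subsetDataset(train, trIdx)
    sc <- fitScaler(tr)
    xtr <- applyScaler(sc, tr@features)
    xva <- applyScaler(sc, train@features[vaIdx, , drop = FALSE])
    model <- entry$fit(xtr, tr@labels, params, seed = seed + f)
    pred <- entry$predictFn(model, xva)
    acc[f] <- mean(pred == train@labels[vaIdx])
  }
  mean(acc)
}

#' Random-search tuning with stratified k-fold cross-validation
#'
#' Draws `nIter` hyperparameter combinations from the classifier's tuning
#' distribution, scores each by mean validation accuracy over `folds`
#' stratified folds (the scaler is refit inside every fold on its training
#' part only, so no fold leaks into its own preprocessing), and returns the
#' best combination; when several combinations tie, the first drawn wins.
#' Duplicate draws are evaluated once. Fully reproducible per seed.
#'
#' @param classifierId one of `names(classifierRoster())`.
#' @param train a [LabelledDataset-class]; every class needs >= `folds` rows.
#' @param nIter number of random draws (default 20).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed driving the draws, the fold assignment and any
#'   classifier-internal randomness.
#' @param roster classifier roster, see [classifierRoster()].
#' @return list with `best` (the winning combination), `meanAccuracy`, and
#'   `evaluations` (data.frame of draw order, combination key, accuracy).
#' @export
randomSearchCV <- function(classifierId, train, nIter = 20L, folds = 5L,
                           seed = 1L, roster = classifierRoster()) {
  entry <- roster[[classifierId]]
  if (is.null(entry)) stop("unknown classifier: ", classifierId)
  seed <- as.integer(seed)
  draws <- withr::with_seed(seed, replicate(nIter, entry$sampleParams(),
                                            simplify = FALSE))
  foldId <- stratifiedFolds(train@labels, k = folds, seed = seed)

  keys <- vapply(draws, .comboKey, "")
  firstIdx <- which(!duplicated(keys))
  accByKey <- numeric(length(firstIdx))
  names(accByKey) <- keys[firstIdx]
  for (i in seq_along(firstIdx)) {
    accByKey[i] <- .cvAccuracy(entry, train, draws[[firstIdx[i]]], foldId,
                               seed = seed + 100L * firstIdx[i])
  }
  bestPos <- which.max(accByKey)   # first occurrence wins ties
  list(best = draws[[firstIdx[bestPos]]],
       meanAccuracy = unname(accByKey[bestPos]),
       evaluations = data.frame(draw = firstIdx, key = names(accByKey),
                                meanAccuracy = unname(accByKey)))
}

.defaultConfig <- function() {
  list(roster = c("PHCA", "SVM", "RF", "KNN", "LDA", "CART"),
       nTrials = 10L, testFraction = 0.1, nIter = 20L, folds = 5L,
       baseSeed = 1L, balance = FALSE, alpha = 0.05)
}

#' Run the full multi-trial evaluation experiment
#'
#' For each trial `t` (seeded `baseSeed + t`): optionally redraw the
#' balanced subsample, make a fresh stratified train/test split, tune every
#' roster classifier by [randomSearchCV()], refit each on the scaled full
#' training set with its winning combination, and evaluate on the scaled
#' test set. Aggregates mean/min/max/IQR per metric per classifier.
#'
#' @param config list with `data` (a [LabelledDataset-class]) and optional
#'   overrides: `roster` (character, default all six classifiers),
#'   `nTrials` (default 10), `testFraction` (0.1), `nIter` (20), `folds`
#'   (5), `baseSeed` (1), `balance` (FALSE: use the data as-is; TRUE:
#'   per-trial balanced subsample, [buildBalanced()]), `outDir` (write
#'   trials.csv, cumulative confusion CSVs, chosen_params.json and a timing
#'   log there).
#' @return Object of class `phcaTrials`: list with `trials` (per-trial
#'   records: seed, chosen params, [MetricsReport-class] per classifier),
#'   `aggregate` (data.frame), `blockMatrices` (per trial, the 5 metrics x
#'   k classifiers matrix used by the rank tests), `catalogue`, `config`.
#' @export
runTrials <- function(config) {
  cfg <- utils::modifyList(.defaultConfig(), config)
  data <- cfg$data
  stopifnot(is(data, "LabelledDataset"))
  roster <- classifierRoster()[cfg$roster]
  if (any(vapply(roster, is.null, TRUE)))
    stop("unknown classifier in roster")
  log <- character()
  trials <- vector("list", cfg$nTrials)
  blocks <- vector("list", cfg$nTrials)
  cumConf <- NULL

  for (t in seq_len(cfg$nTrials)) {
    seedT <- as.integer(cfg$baseSeed) + t
    dT <- if (isTRUE(cfg$balance)) buildBalanced(data, seed = seedT) else data
    t0 <- proc.time()[["elapsed"]]
    sp <- stratifiedSplit(dT, cfg$testFraction, seed = seedT)
    chosen <- list()
    reports <- list()
    for (id in names(roster)) {
      tc0 <- proc.time()[["elapsed"]]
      rs <- tryCatch(
        randomSearchCV(id, sp$train, nIter = cfg$nIter, folds = cfg$folds,
                       seed = seedT, roster = roster),
        error = function(e) stop("trial ", t, ", classifier ", id, ": ",
                                 conditionMessage(e)))
      sc <- fitScaler(sp$train)
      xtr <- applyScaler(sc, sp$train@features)
      xte <- applyScaler(sc, sp$test@features)
      model <- roster[[id]]$fit(xtr, sp$train@labels, rs$best, seed = seedT)
      pred <- roster[[id]]$predictFn(model, xte)
      reports[[id]] <- evaluateMetrics(sp$test@labels, pred, dT@catalogue)
      chosen[[id]] <- rs$best
      log <- c(log, sprintf(
        "trial %d classifier %s seed %d train %d test %d cvAcc %.4f %.1fs",
        t, id, seedT, nSamples(sp$train), nSamples(sp$test),
        rs$meanAccuracy, proc.time()[["elapsed"]] - tc0))
      conf <- reports[[id]]@confusion
      if (is.null(cumConf)) cumConf <- list()
      cumConf[[id]] <- if (is.null(cumConf[[id]])) conf else
        cumConf[[id]] + conf
    }
    blocks[[t]] <- vapply(reports, metricVector, numeric(5L))
    trials[[t]] <- list(trial = t, seed = seedT, chosen = chosen,
                        metrics = reports)
    log <- c(log, sprintf("trial %d done in %.1fs", t,
                          proc.time()[["elapsed"]] - t0))
  }

  longRows <- do.call(rbind, lapply(trials, function(tr) {
    do.call(rbind, lapply(names(tr$metrics), function(id) {
      mv <- metricVector(tr$metrics[[id]])
      data.frame(trial = tr$trial, classifier = id, metric = names(mv),
                 value = unname(mv))
    }))
  }))
  agg <- do.call(rbind, lapply(split(longRows,
                                     longRows[c("classifier", "metric")]),
                               function(g) data.frame(
    classifier = g$classifier[1L], metric = g$metric[1L],
    mean = mean(g$value), min = min(g$value), max = max(g$value),
    iqr = stats::IQR(g$value))))
  rownames(agg) <- NULL

  out <- structure(list(trials = trials, long = longRows, aggregate = agg,
                        blockMatrices = blocks, cumulativeConfusion = cumConf,
                        catalogue = data@catalogue, config = cfg, log = log),
                   class = "phcaTrials")
  if (!is.null(cfg$outDir)) writeTrialOutputs(out, cfg$outDir)
  out
}

#' Write trial artifacts to disk
#'
#' Emits `trials.csv` (one row per trial x classifier x metric),
#' `confusion_<classifier>.csv` (cumulative over trials),
#' `chosen_params.json` and `run_log.txt`.
#'
#' @param result a `phcaTrials` object from [runTrials()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTrialOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$long, file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(result$cumulativeConfusion))
    utils::write.csv(result$cumulativeConfusion[[id]],
                     file.path(dir, paste0("confusion_", id, ".csv")),
                     quote = FALSE)
  chosen <- lapply(result$trials, function(tr)
    list(trial = tr$trial, seed = tr$seed, params = tr$chosen))
  jsonlite::write_json(chosen, file.path(dir, "chosen_params.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.phcaTrials <- function(x, ...) {
  cat(sprintf("phcaTrials: %d trials, classifiers %s\n", length(x$trials),
              paste(colnames(x$blockMatrices[[1L]]), collapse = ", ")))
  acc <- x$aggregate[x$aggregate$metric == "accuracy", ]
  for (i in seq_len(nrow(acc)))
    cat(sprintf("  %-5s accuracy mean %.4f [%.4f, %.4f]\n",
                acc$classifier[i], acc$mean[i], acc$min[i], acc$max[i]))
  invisible(x)
}
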