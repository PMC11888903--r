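# Harness: stratified splitting, scaling, tuning, metrics, trial driver.

test_that("stratified split keeps exact per-class quotas", {
  data <- separableBlobs(k = 6L, size = 100L, m = 6L, seed = 1)
  sp <- stratifiedSplit(data, 0.1, seed = 4)
  expect_equal(unname(table(classLabels(sp$test))[classCatalogue(data)]),
               rep(10L, 6L), ignore_attr = TRUE)
  expect_equal(nSamples(sp$train) + nSamples(sp$test), 600L)
  expect_length(intersect(sp$test@ids, sp$train@ids), 0L)
})

test_that("largest-remainder rounding keeps imbalanced quotas within 1 row", {
  counts <- c(313L, 290L, 450L)
  data <- makeGaussianClasses(3L, counts, m = 4L, seed = 2)
  sp <- stratifiedSplit(data, 0.1, seed = 9)
  got <- as.numeric(table(factor(classLabels(sp$test),
                                 levels = classCatalogue(data))))
  expect_true(all(abs(got - 0.1 * counts) <= 1))
  expect_equal(sum(got), round(sum(counts) * 0.1))
})

test_that("splits are seed-reproducible and row-order invariant", {
  data <- separableBlobs(k = 3L, size = 21L, m = 4L, seed = 6)
  a <- stratifiedSplit(data, 0.2, seed = 5)
  b <- stratifiedSplit(data, 0.2, seed = 5)
  expect_identical(a$testIdx, b$testIdx)
  expect_false(identical(a$testIdx, stratifiedSplit(data, 0.2, 6)$testIdx))

  perm <- withr::with_seed(8, sample(nSamples(data)))
  shuffled <- LabelledDataset(featureMatrix(data)[perm, ],
                              classLabels(data)[perm],
                              catalogue = classCatalogue(data),
                              ids = data@ids[perm])
  c1 <- stratifiedSplit(shuffled, 0.2, seed = 5)
  expect_setequal(c1$test@ids, a$test@ids)  # same multiset partition

  single <- LabelledDataset(matrix(1:4, ncol = 1), c("A", "A", "A", "B"))
  expect_error(stratifiedSplit(single, 0.5, 1), "at least 2 rows")
})

test_that("scaler centres to 0, unit variance, zero-sd passthrough", {
  sc <- fitScaler(matrix(c(0, 2), ncol = 1))
  expect_equal(unname(sc$mean), 1)
  expect_equal(unname(applyScaler(sc, matrix(c(0, 2), ncol = 1))[, 1]),
               c(-1, 1))
  expect_equal(unname(applyScaler(sc, matrix(1, 1, 1))[, 1]), 0)

  x <- cbind(rnorm(20), rep(5, 20))
  sc2 <- fitScaler(x)
  z <- applyScaler(sc2, x)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(mean(z[, 1]^2), 1, tolerance = 1e-12)  # unit variance
  expect_equal(unname(z[, 2]), rep(0, 20))  # centred, not divided
})

test_that("stratified folds cover all rows evenly within classes", {
  labs <- rep(c("A", "B", "C"), each = 20L)
  f <- stratifiedFolds(labs, k = 5L, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (cl in c("A", "B", "C"))
    expect_equal(unname(table(f[labs == cl])), rep(4L, 5L),
                 ignore_attr = TRUE)
  expect_identical(f, stratifiedFolds(labs, 5L, 3))
  expect_error(stratifiedFolds(c("A", "A", "B"), k = 2L, seed = 1), "at least")
})

test_that("random search returns the single or dominant combination", {
  data <- separableBlobs(k = 2L, size = 10L, m = 3L, seed = 4)
  one <- randomSearchCV("SWITCH", data, nIter = 5L, folds = 2L, seed = 1,
                        roster = switchRoster(goodOnly = TRUE))
  expect_true(one$best$good)

  res <- randomSearchCV("SWITCH", data, nIter = 8L, folds = 2L, seed = 2,
                        roster = switchRoster())
  expect_true(res$best$good)        # nearest-neighbour beats the constant
  expect_gt(res$meanAccuracy, 0.9)
  res2 <- randomSearchCV("SWITCH", data, nIter = 8L, folds = 2L, seed = 2,
                         roster = switchRoster())
  expect_identical(res, res2)       # seed-reproducible
})

test_that("PHCA tuning matches direct enumeration of the three choices", {
  data <- separableBlobs(k = 3L, size = 15L, m = 4L, seed = 5)
  res <- randomSearchCV("PHCA", data, nIter = 20L, folds = 5L, seed = 5)

  foldId <- stratifiedFolds(classLabels(data), 5L, seed = 5)
  direct <- vapply(homologyDimensionChoices(), function(ch) {
    acc <- numeric(5L)
    for (f in 1:5) {
      tr <- which(foldId != f); va <- which(foldId == f)
      sc <- fitScaler(featureMatrix(data)[tr, ])
      xtr <- applyScaler(sc, featureMatrix(data)[tr, ])
      xva <- applyScaler(sc, featureMatrix(data)[va, ])
      m <- phcaFit(xtr, classLabels(data)[tr], ch)
      acc[f] <- mean(predict(m, xva) == classLabels(data)[va])
    }
    mean(acc)
  }, 0)
  # scoring on components attains the best validation accuracy, and the
  # returned combination is the first-drawn member of the argmax set
  expect_equal(unname(direct["H0_ONLY"]), max(direct))
  expect_equal(res$meanAccuracy, max(direct), tolerance = 1e-12)
  draws <- withr::with_seed(5L, replicate(
    20L, classifierRoster()$PHCA$sampleParams(), simplify = FALSE))
  drawnChoices <- vapply(draws, `[[`, "", "choice")
  argmax <- names(direct)[direct >= max(direct) - 1e-12]
  expect_equal(res$best$choice,
               drawnChoices[drawnChoices %in% argmax][1L])
})

test_that("fold scalers never see validation rows", {
  data <- separableBlobs(k = 2L, size = 12L, m = 3L, seed = 7)
  seen <- new.env()
  seen$mats <- list()
  spy <- list(SPY = list(
    sampleParams = function() list(),
    fit = function(x, y, params, seed) {
      seen$mats[[length(seen$mats) + 1L]] <- x
      list(y = y)
    },
    predictFn = function(model, x) rep(model$y[1L], nrow(x))
  ))
  randomSearchCV("SPY", data, nIter = 1L, folds = 3L, seed = 9, roster = spy)
  base <- seen$mats

  # corrupt one validation fold massively; training-fold scalers unchanged
  foldId <- stratifiedFolds(classLabels(data), 3L, seed = 9)
  feat <- featureMatrix(data)
  feat[foldId == 1L, ] <- feat[foldId == 1L, ] + 1e6
  corrupted <- LabelledDataset(feat, classLabels(data),
                               catalogue = classCatalogue(data),
                               ids = data@ids)
  seen$mats <- list()
  randomSearchCV("SPY", corrupted, nIter = 1L, folds = 3L, seed = 9,
                 roster = spy)
  expect_equal(seen$mats[[1L]], base[[1L]], tolerance = 1e-12)
})

test_that("metric arithmetic matches the one-vs-rest definitions", {
  perfect <- evaluateMetrics(c("A", "B"), c("A", "B"))
  expect_equal(unname(metricVector(perfect)), rep(1, 5))

  truth <- c("A", "A", "A", "A", "B", "B", "B", "B")
  pred <- c("A", "A", "A", "B", "B", "B", "B", "B")
  rep1 <- evaluateMetrics(truth, pred, c("A", "B"))
  expect_equal(rep1@accuracy, 0.875)
  expect_equal(unname(rep1@macro["precision"]), 0.9)
  expect_equal(unname(rep1@macro["recall"]), 0.875)
  expect_equal(unname(rep1@macro["f1"]), (6 / 7 + 8 / 9) / 2,
               tolerance = 1e-12)
  expect_equal(unname(rep1@macro["specificity"]), 0.875)
  expect_equal(sum(rep1@confusion), 8L)
  expect_equal(unname(rowSums(rep1@perClass[, c("TP", "FP", "FN", "TN")])),
               rep(8, 2))

  wrong <- evaluateMetrics(c("A", "B"), c("B", "A"))
  expect_equal(wrong@accuracy, 0)
  expect_equal(unname(wrong@macro["specificity"]), 0)
  expect_error(evaluateMetrics("A", c("A", "B")), "equal length")
})

test_that("misclassification ranking: order, ties, and linearity", {
  diagOnly <- diag(3L)
  dimnames(diagOnly) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(nrow(misclassificationReport(diagOnly)), 0L)

  conf <- matrix(0L, 2, 2, dimnames = list(c("M", "F"), c("M", "F")))
  conf["M", "F"] <- 6L
  expect_equal(misclassificationReport(conf),
               data.frame(true = "M", predicted = "F", count = 6L))

  a <- matrix(c(5L, 2L, 1L, 7L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  b <- matrix(c(4L, 0L, 3L, 6L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  summed <- misclassificationReport(a + b)
  expect_equal(summed$count, c(4L, 2L))   # element-wise sum, sorted
  expect_equal(summed$true, c("A", "B"))
})

test_that("one-trial PHCA run on separable blobs is perfect and aggregated", {
  data <- separableBlobs(k = 3L, size = 20L, m = 4L, seed = 15)
  res <- runTrials(list(data = data, roster = "PHCA", nTrials = 1L,
                        nIter = 3L, folds = 3L, baseSeed = 15L))
  expect_equal(res$trials[[1L]]$metrics$PHCA@accuracy, 1)
  agg <- res$aggregate
  expect_equal(agg$mean[agg$metric == "accuracy"], 1)
})

test_that("trials draw distinct splits and aggregate by arithmetic mean", {
  data <- separableBlobs(k = 3L, size = 20L, m = 4L, seed = 16)
  res <- runTrials(list(data = data, roster = c("PHCA", "CART"),
                        nTrials = 2L, nIter = 2L, folds = 3L,
                        baseSeed = 16L))
  s1 <- stratifiedSplit(data, 0.1, res$trials[[1L]]$seed)$testIdx
  s2 <- stratifiedSplit(data, 0.1, res$trials[[2L]]$seed)$testIdx
  expect_false(identical(s1, s2))
  accs <- vapply(res$trials, function(tr) tr$metrics$CART@accuracy, 0)
  agg <- res$aggregate
  expect_equal(agg$mean[agg$classifier == "CART" & agg$metric == "accuracy"],
               mean(accs))
  expect_equal(dim(res$blockMatrices[[1L]]), c(5L, 2L))
})

test_that("every roster member trains and predicts under the contract", {
  data <- separableBlobs(k = 3L, size = 18L, m = 4L, seed = 19)
  sp <- stratifiedSplit(data, 0.2, seed = 19)
  sc <- fitScaler(sp$train)
  xtr <- applyScaler(sc, sp$train@features)
  xte <- applyScaler(sc, sp$test@features)
  roster <- classifierRoster()
  params <- list(
    PHCA = list(choice = "H0_ONLY"),
    SVM = list(C = 10, gamma = "scale", kernel = "rbf"),
    RF = list(n_estimators = 50L, max_depth = 5L, min_samples_split = 2L),
    KNN = list(n_neighbors = 3L),
    LDA = list(solver = "lsqr", shrinkage = 0.3),
    CART = list(max_depth = 5L, min_samples_leaf = 1L,
                min_samples_split = 2L))
  for (id in names(roster)) {
    model <- roster[[id]]$fit(xtr, sp$train@labels, params[[id]], seed = 1L)
    pred <- roster[[id]]$predictFn(model, xte)
    expect_length(pred, nSamples(sp$test))
    expect_true(all(pred %in% classCatalogue(data)), label = id)
    expect_gte(mean(pred == sp$test@labels), 0.5)
  }
})
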