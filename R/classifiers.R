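# Baseline classifier roster behind a uniform contract so PHCA and the
# classical models share identical splits, scaling and tuning budget.
# Each entry provides
#   sampleParams()            draw one hyperparameter combination
#   fit(x, y, params, seed)   train on a scaled feature matrix
#   predictFn(model, x)       predict labels for scaled queries
# Hyperparameter distributions follow the published tuning table:
#   SVM  C ~ U(2^-3, 2^15), gamma in {auto, scale}, RBF kernel
#   RF   n_estimators 1-350, max_depth 1-5, min_samples_split 2-10
#   KNN  n_neighbors 1-500 (clamped to the training size at fit time)
#   LDA  solver in {svd, lsqr, eigen}, shrinkage ~ U(0,1) (ignored for svd)
#   CART max_depth 1-30, min_samples_leaf 1-60, min_samples_split 2-60
#   PHCA homology dimension in {H0 only, H1 only, H0 and H1}

.asFactor <- function(y, catalogue) factor(y, levels = catalogue)

# Regularised linear discriminant: pooled within-class covariance, optionally
# shrunk toward its scaled identity, Gaussian class scores with proportional
# priors. solver "svd" inverts through an eigendecomposition pseudo-inverse
# (no shrinkage); "lsqr"/"eigen" solve with the shrunk covariance.
.ldaFit <- function(x, y, solver = "svd", shrinkage = 0) {
  y <- as.factor(y)
  p <- ncol(x)
  mu <- t(vapply(levels(y), function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(p)))
  centred <- x - mu[as.integer(y), , drop = FALSE]
  S <- crossprod(centred) / nrow(x)
  if (solver %in% c("lsqr", "eigen") && shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * (sum(diag(S)) / p) * diag(p)
  eig <- eigen(S, symmetric = TRUE)
  keep <- eig$values > max(eig$values, 0) * 1e-10
  if (!any(keep)) keep[1L] <- TRUE
  Sinv <- eig$vectors[, keep, drop = FALSE] %*%
    (t(eig$vectors[, keep, drop = FALSE]) / eig$values[keep])
  prior <- as.numeric(table(y)) / length(y)
  list(mu = mu, Sinv = Sinv, logPrior = log(prior), levels = levels(y))
}

.ldaPredict <- function(model, x) {
  lin <- x %*% model$Sinv %*% t(model$mu)
  const <- -0.5 * rowSums((model$mu %*% model$Sinv) * model$mu) +
    model$logPrior
  scores <- sweep(lin, 2L, const, "+")
  model$levels[max.col(scores, ties.method = "first")]
}

.popVar <- function(x) mean((x - mean(x))^2)

#' The classifier roster
#'
#' Named list of classifier adapters (`PHCA`, `SVM`, `RF`, `KNN`, `LDA`,
#' `CART`) sharing a uniform sample/fit/predict contract, used by
#' [randomSearchCV()] and [runTrials()]. `sampleParams` must be called
#' inside a seeded RNG context; `fit` takes a scaled feature matrix, labels,
#' a parameter combination, and an integer seed that makes any internal
#' randomness (forest bootstraps, k-NN vote ties) reproducible.
#'
#' @return Named list of roster entries.
#' @export
classifierRoster <- function() {
  list(
    PHCA = list(
      sampleParams = function()
        list(choice = sample(homologyDimensionChoices(), 1L)),
      fit = function(x, y, params, seed)
        phcaFit(x, y, choice = params$choice, catalogue = levels(as.factor(y))),
      predictFn = function(model, x) predict(model, x)
    ),
    SVM = list(
      sampleParams = function()
        list(C = stats::runif(1L, 2^-3, 2^15),
             gamma = sample(c("auto", "scale"), 1L), kernel = "rbf"),
      fit = function(x, y, params, seed) {
        g <- if (params$gamma == "auto") 1 / ncol(x)
             else 1 / (ncol(x) * max(.popVar(x), 1e-12))
        cat <- levels(as.factor(y))
        list(fit = e1071::svm(x, .asFactor(y, cat), scale = FALSE,
                              type = "C-classification", kernel = "radial",
                              cost = params$C, gamma = g),
             catalogue = cat)
      },
      predictFn = function(model, x)
        as.character(stats::predict(model$fit, x))
    ),
    RF = list(
      sampleParams = function()
        list(n_estimators = sample(1:350, 1L), max_depth = sample(1:5, 1L),
             min_samples_split = sample(2:10, 1L)),
      fit = function(x, y, params, seed) {
        cat <- levels(as.factor(y))
        df <- data.frame(x)
        df$.outcome <- .asFactor(y, cat)
        list(fit = ranger::ranger(dependent.variable.name = ".outcome", data = df,
                                  num.trees = params$n_estimators,
                                  max.depth = params$max_depth,
                                  min.node.size = params$min_samples_split,
                                  num.threads = 1L, seed = seed),
             catalogue = cat)
      },
      predictFn = function(model, x)
        as.character(stats::predict(model$fit, data.frame(x),
                                    num.threads = 1L)$predictions)
    ),
    KNN = list(
      sampleParams = function() list(n_neighbors = sample(1:500, 1L)),
      fit = function(x, y, params, seed)
        list(x = x, y = as.character(y),
             k = min(params$n_neighbors, nrow(x)), seed = seed),
      predictFn = function(model, x)
        withr::with_seed(model$seed, as.character(
          class::knn(model$x, x, model$y, k = model$k)))
    ),
    LDA = list(
      sampleParams = function()
        list(solver = sample(c("svd", "lsqr", "eigen"), 1L),
             shrinkage = stats::runif(1L)),
      fit = function(x, y, params, seed)
        .ldaFit(x, y, solver = params$solver, shrinkage = params$shrinkage),
      predictFn = .ldaPredict
    ),
    CART = list(
      sampleParams = function()
        list(max_depth = sample(1:30, 1L),
             min_samples_leaf = sample(1:60, 1L),
             min_samples_split = sample(2:60, 1L)),
      fit = function(x, y, params, seed) {
        cat <- levels(as.factor(y))
        df <- data.frame(x)
        df$.outcome <- .asFactor(y, cat)
        ctl <- rpart::rpart.control(
          maxdepth = min(params$max_depth, 30L),
          minbucket = params$min_samples_leaf,
          minsplit = params$min_samples_split, cp = 0, xval = 0L)
        list(fit = rpart::rpart(.outcome ~ ., data = df, method = "class",
                                control = ctl),
             catalogue = cat)
      },
      predictFn = function(model, x)
        as.character(stats::predict(model$fit, data.frame(x), type = "class"))
    )
  )
}
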