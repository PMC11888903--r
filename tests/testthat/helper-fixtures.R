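# Shared fixtures: small geometric clouds with known persistence, and a
# helper comparing diagrams as multisets after dropping zero-lifespan rows
# (backends legitimately differ on emitting those).

unitSquare <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

equilateralTriangle <- function(side = 1) {
  side * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
}

randomCloud <- function(n, m = 2L, seed = 1L) {
  withr::with_seed(seed, matrix(stats::rnorm(n * m), ncol = m))
}

# nonzero bars of a diagram, canonically ordered, for multiset comparison
nonzeroBars <- function(diagram, tol = 1e-12) {
  r <- diagramRows(diagram)
  r <- r[r$death - r$birth > tol | r$capped, , drop = FALSE]
  r <- r[order(r$dim, r$birth, r$death, r$capped), , drop = FALSE]
  rownames(r) <- NULL
  r
}

expectSameBars <- function(a, b, tol = 1e-10) {
  ra <- nonzeroBars(a)
  rb <- nonzeroBars(b)
  expect_equal(nrow(ra), nrow(rb))
  expect_equal(ra$dim, rb$dim)
  expect_equal(ra$birth, rb$birth, tolerance = tol)
  expect_equal(ra$death, rb$death, tolerance = tol)
}

# well-separated Gaussian blobs for classifier tests
separableBlobs <- function(k = 3L, size = 30L, m = 5L, seed = 1L,
                           separation = 10, withinSd = 1) {
  makeGaussianClasses(k = k, sizes = size, m = m, separation = separation,
                      withinSd = withinSd, seed = seed)
}

# toy roster with a single tunable binary switch: params$good = TRUE predicts
# the true label of the nearest training point, FALSE predicts the first
# catalogue class for everything
switchRoster <- function(goodOnly = FALSE) {
  list(SWITCH = list(
    sampleParams = if (goodOnly) function() list(good = TRUE)
                   else function() list(good = sample(c(TRUE, FALSE), 1L)),
    fit = function(x, y, params, seed)
      list(x = x, y = y, good = params$good),
    predictFn = function(model, x) {
      if (!model$good) return(rep(model$y[1L], nrow(x)))
      idx <- apply(x, 1L, function(q)
        which.min(colSums((t(model$x) - q)^2)))
      model$y[idx]
    }
  ))
}
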