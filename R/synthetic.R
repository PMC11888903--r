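# Synthetic data: isotropic Gaussian class blobs in landmark-style feature
# space, stylised 21-landmark hand datasets (the post-extraction form of a
# static sign-alphabet image set: 63 features per item, within-class
# geometric coherence, optional class imbalance and a conversion-failure
# fraction), and geometric fixture clouds (circle, sphere, torus) for the
# persistence engine.

#' Gaussian class blobs
#'
#' Class `i` is drawn from an isotropic Gaussian with standard deviation
#' `withinSd` at a centre placed so that all pairwise centre distances equal
#' `separation` (centres sit at `separation/sqrt(2)` times distinct basis
#' vectors; this needs `k <= m`).
#'
#' @param k number of classes (>= 2).
#' @param sizes per-class sizes: a scalar (equal classes) or a length-k
#'   vector (imbalance).
#' @param m feature dimension (default 63, the hand-landmark width).
#' @param separation pairwise distance between class centres.
#' @param withinSd within-class standard deviation per coordinate.
#' @param seed integer seed.
#' @return A [LabelledDataset-class] with classes `"C1" ... "Ck"`.
#' @export
makeGaussianClasses <- function(k, sizes, m = 63L, separation = 10,
                                withinSd = 1, seed = 1L) {
  stopifnot(k >= 2, separation > 0, withinSd > 0, k <= m)
  sizes <- rep_len(as.integer(sizes), k)
  stopifnot(all(sizes >= 1L))
  centres <- matrix(0, k, m)
  for (i in seq_len(k)) centres[i, i] <- separation / sqrt(2)
  labels <- rep(paste0("C", seq_len(k)), times = sizes)
  x <- withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(sum(sizes) * m, sd = withinSd),
                    ncol = m)
    centres[rep(seq_len(k), times = sizes), , drop = FALSE] + noise
  })
  LabelledDataset(x, labels, catalogue = paste0("C", seq_len(k)))
}

# stylised 21-landmark skeleton: wrist at the origin, five finger chains of
# four joints; per-class flexion pattern (each finger curled or extended)
# encoded by the class index. Only the geometric coherence matters.
.handTemplate <- function(classIndex) {
  baseAngles <- seq(-0.9, 0.9, length.out = 5L)   # fan of the five fingers
  curled <- as.integer(intToBits(classIndex - 1L))[1:5] == 1L
  coords <- matrix(0, 21L, 3L)
  row <- 2L
  for (f in seq_len(5L)) {
    dir2 <- c(sin(baseAngles[f]), cos(baseAngles[f]))
    segment <- if (curled[f]) c(0.25, 0.18, 0.10, 0.06)
               else c(0.25, 0.22, 0.20, 0.18)
    bend <- if (curled[f]) c(0, 0.04, 0.10, 0.16) else rep(0, 4L)
    pos <- c(0, 0)
    for (j in seq_len(4L)) {
      pos <- pos + segment[j] * dir2
      coords[row, ] <- c(pos, bend[j] + 0.02 * f)
      row <- row + 1L
    }
  }
  coords
}

#' Stylised hand-landmark dataset
#'
#' Emulates a landmark-extracted static sign alphabet: each class has a
#' distinct 21x3 skeleton pose (wrist plus five finger chains of four
#' joints, a different flexion pattern per class); each item is the
#' flattened 63-vector of the jittered template, optionally after a random
#' global translation and scale. A fraction `rho` of the requested items
#' per class is marked not-converted (the landmark front-end found no
#' hand), excluded from the dataset but counted in the report.
#'
#' @param k number of classes (2..32).
#' @param classSize items requested per class (scalar or length-k vector).
#' @param jitterSd per-coordinate Gaussian jitter (default 0.01).
#' @param translateRange half-width of the uniform per-item translation
#'   applied to x and y (default 0: off).
#' @param scaleRange multiplicative per-item scale drawn from
#'   `U(1 - scaleRange, 1 + scaleRange)` (default 0: off).
#' @param rho conversion-failure fraction in [0, 1).
#' @param seed integer seed.
#' @return list with `dataset` (a [LabelledDataset-class]) and `report`
#'   (data.frame: class, requested, converted, notConverted).
#' @export
makeHandLike <- function(k, classSize = 50L, jitterSd = 0.01,
                         translateRange = 0, scaleRange = 0, rho = 0,
                         seed = 1L) {
  stopifnot(k >= 2, k <= 32, rho >= 0, rho < 1, jitterSd > 0)
  classSize <- rep_len(as.integer(classSize), k)
  stopifnot(all(classSize >= 1L))
  labels <- LETTERS[seq_len(min(k, 26L))]
  if (k > 26L) labels <- c(labels, paste0("Z", seq_len(k - 26L)))

  feats <- list()
  labs <- character()
  report <- data.frame(class = labels, requested = classSize,
                       converted = 0L, notConverted = 0L)
  withr::with_seed(as.integer(seed), {
    for (ci in seq_len(k)) {
      template <- .handTemplate(ci)
      nReq <- classSize[ci]
      nNot <- as.integer(floor(rho * nReq + 0.5))
      notIdx <- if (nNot > 0) sample(nReq, nNot) else integer()
      rows <- matrix(0, nReq, 63L)
      for (r in seq_len(nReq)) {
        pose <- template
        if (scaleRange > 0)
          pose <- pose * stats::runif(1L, 1 - scaleRange, 1 + scaleRange)
        if (translateRange > 0)
          pose[, 1:2] <- pose[, 1:2] +
            matrix(stats::runif(2L, -translateRange, translateRange),
                   21L, 2L, byrow = TRUE)
        pose <- pose + matrix(stats::rnorm(63L, sd = jitterSd), 21L, 3L)
        rows[r, ] <- as.numeric(t(pose))   # x0,y0,z0,...,x20,y20,z20
      }
      keep <- setdiff(seq_len(nReq), notIdx)
      feats[[ci]] <- rows[keep, , drop = FALSE]
      labs <- c(labs, rep(labels[ci], length(keep)))
      report$converted[ci] <- length(keep)
      report$notConverted[ci] <- nNot
    }
  })
  x <- do.call(rbind, feats)
  colnames(x) <- paste0(rep(c("x", "y", "z"), 21L),
                        rep(0:20, each = 3L))
  list(dataset = LabelledDataset(x, labs, catalogue = labels),
       report = report)
}

#' Balanced / imbalanced dataset builders
#'
#' `buildBalanced` subsamples every class down to the minimum class count
#' (uniformly, seeded), mirroring the balanced-design construction where
#' each class keeps only as many items as the smallest class converted.
#' `buildImbalanced` is the identity pass-through: classification on all
#' converted items, unequal counts preserved.
#'
#' @param data a [LabelledDataset-class].
#' @param seed integer seed for the subsample.
#' @return A [LabelledDataset-class].
#' @export
buildBalanced <- function(data, seed = 1L) {
  stopifnot(is(data, "LabelledDataset"))
  counts <- table(factor(data@labels, levels = data@catalogue))
  target <- min(counts)
  keep <- integer()
  withr::with_seed(as.integer(seed), {
    for (cl in data@catalogue) {
      pool <- .canonicalClassOrder(data, cl)
      keep <- c(keep, if (length(pool) > target) sample(pool, target)
                      else pool)
    }
  })
  .subsetDataset(data, sort(keep))
}

#' @rdname buildBalanced
#' @export
buildImbalanced <- function(data) {
  stopifnot(is(data, "LabelledDataset"))
  data
}

#' Geometric fixture clouds
#'
#' Uniform samples on a unit circle, unit sphere, or a torus (tube radius
#' 1 around a centre circle of radius 2), plus isotropic Gaussian noise.
#' These are the standard shapes whose persistence diagrams show a dominant
#' 1-dimensional class (circle, torus) and are used as engine fixtures.
#'
#' @param shape `"circle"`, `"sphere"` or `"torus"`.
#' @param n number of points (>= 10).
#' @param noiseSd Gaussian noise standard deviation (default 0).
#' @param seed integer seed.
#' @return A [PointCloud-class].
#' @export
makeShapeCloud <- function(shape = c("circle", "sphere", "torus"), n = 100L,
                           noiseSd = 0, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n >= 10L)
  x <- withr::with_seed(as.integer(seed), {
    base <- switch(shape,
      circle = {
        th <- stats::runif(n, 0, 2 * pi)
        cbind(cos(th), sin(th))
      },
      sphere = {
        g <- matrix(stats::rnorm(3L * n), ncol = 3L)
        g / sqrt(rowSums(g^2))
      },
      torus = {
        u <- stats::runif(n, 0, 2 * pi)
        v <- stats::runif(n, 0, 2 * pi)
        cbind((2 + cos(v)) * cos(u), (2 + cos(v)) * sin(u), sin(v))
      })
    if (noiseSd > 0)
      base <- base + matrix(stats::rnorm(length(base), sd = noiseSd),
                            nrow = n)
    base
  })
  PointCloud(x)
}
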