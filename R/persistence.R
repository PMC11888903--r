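# Vietoris-Rips persistent homology under the radius convention: two points
# are joined at scale eps once d(x, y) <= 2*eps, so every entry scale is half
# a distance and the auto horizon is half the cloud diameter.

.cloudMatrix <- function(cloud) {
  x <- if (is(cloud, "PointCloud")) cloud@coordinates else as.matrix(cloud)
  storage.mode(x) <- "double"
  if (length(x) && !all(is.finite(x)))
    stop("point cloud coordinates must be finite")
  x
}

.distMatrix <- function(x) as.matrix(stats::dist(x))

#' @rdname maxScale
#' @export
setMethod("maxScale", "PointCloud", function(cloud) {
  maxScale(cloud@coordinates)
})

#' @rdname maxScale
#' @export
setMethod("maxScale", "matrix", function(cloud) {
  x <- .cloudMatrix(cloud)
  if (nrow(x) < 2L) return(0)
  0.5 * max(stats::dist(x))
})

.resolveMaxScale <- function(x, params) {
  if (is.na(params@maxScale)) maxScale(x) else params@maxScale
}

#' Vietoris-Rips persistence diagram of a point cloud
#'
#' Computes all homology classes (components, and loops when
#' `maxDimension = 1`) of the Vietoris-Rips filtration of the cloud, births
#' and deaths in radius units. Classes still alive at the filtration horizon
#' are reported with death equal to the horizon and the `capped` flag set;
#' under the auto horizon (half the cloud diameter) a nonempty cloud has
#' exactly one capped dimension-0 row, the essential component.
#' Zero-lifespan rows are retained.
#'
#' @param cloud a [PointCloud-class] or coordinate matrix.
#' @param params a [FiltrationParams-class]; default computes H0 and H1 up to
#'   the auto horizon.
#' @return A [PersistenceDiagram-class].
#' @examples
#' sq <- PointCloud(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' diagramRows(vrPersistence(sq)) # one loop born 0.5, dead sqrt(2)/2
#' @seealso [h0PersistenceMST()] for the fast dimension-0 path,
#'   [bruteForcePersistence()] for the small-cloud oracle.
#' @export
vrPersistence <- function(cloud, params = FiltrationParams()) {
  stopifnot(is(params, "FiltrationParams"))
  validObject(params)
  x <- .cloudMatrix(cloud)
  if (nrow(x) == 0L)
    return(.makeDiagram(integer(), numeric(), numeric(), logical(), 0))
  ms <- .resolveMaxScale(x, params)
  if (nrow(x) == 1L)
    return(.makeDiagram(0L, 0, ms, TRUE, ms))
  bars <- .vrReduceCpp(.distMatrix(x), ms, params@maxDimension)
  .makeDiagram(bars[, "dim"], bars[, "birth"], bars[, "death"],
               bars[, "capped"] > 0, ms)
}

# Prim's algorithm; returns the MST edge weights of a distance matrix
.mstEdgeWeights <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(numeric())
  inTree <- logical(n)
  inTree[1L] <- TRUE
  best <- d[, 1L]
  w <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    cand <- which(!inTree)
    nxt <- cand[which.min(best[cand])]
    w[step] <- best[nxt]
    inTree[nxt] <- TRUE
    best <- pmin(best, d[, nxt])
  }
  w
}

#' Dimension-0 persistence via the minimum spanning tree
#'
#' Vietoris-Rips H0 is single linkage: components merge exactly at half the
#' minimum-spanning-tree edge weights. This fast path produces the same
#' dimension-0 row multiset as [vrPersistence()] under the auto horizon,
#' with one capped essential row at the horizon.
#'
#' @param cloud a [PointCloud-class] or coordinate matrix (nonempty).
#' @return A [PersistenceDiagram-class] with dimension-0 rows only.
#' @export
h0PersistenceMST <- function(cloud) {
  x <- .cloudMatrix(cloud)
  if (nrow(x) == 0L)
    return(.makeDiagram(integer(), numeric(), numeric(), logical(), 0))
  ms <- maxScale(x)
  if (nrow(x) == 1L) return(.makeDiagram(0L, 0, ms, TRUE, ms))
  deaths <- 0.5 * .mstEdgeWeights(.distMatrix(x))
  .makeDiagram(rep.int(0L, nrow(x)), numeric(nrow(x)),
               c(sort(deaths), ms), c(rep(FALSE, nrow(x) - 1L), TRUE), ms)
}

# closed form used by the fast classifier path:
# total H0 lifespan = maxsc + half the MST weight sum
.h0TotalLifespan <- function(x) {
  if (nrow(x) == 0L) return(0)
  if (nrow(x) == 1L) return(0)
  d <- .distMatrix(x)
  0.5 * max(d) + 0.5 * sum(.mstEdgeWeights(d))
}

#' Brute-force persistence oracle for tiny clouds
#'
#' Independent reference implementation: enumerates every simplex of the
#' clique filtration up to dimension `maxDimension + 1`, builds the dense
#' boundary matrix over F2 in filtration order (ties by scale, then simplex
#' dimension, then lexicographic vertex tuple) and performs the textbook
#' left-to-right column reduction. Exact but exponential; restricted to at
#' most 10 points. Agrees with [vrPersistence()] up to zero-lifespan rows.
#'
#' @param cloud a [PointCloud-class] or coordinate matrix with <= 10 points.
#' @param params a [FiltrationParams-class].
#' @return A [PersistenceDiagram-class].
#' @export
bruteForcePersistence <- function(cloud, params = FiltrationParams()) {
  stopifnot(is(params, "FiltrationParams"))
  validObject(params)
  x <- .cloudMatrix(cloud)
  n <- nrow(x)
  if (n > 10L) stop("brute-force oracle is limited to 10 points")
  if (n == 0L)
    return(.makeDiagram(integer(), numeric(), numeric(), logical(), 0))
  ms <- .resolveMaxScale(x, params)
  if (n == 1L) return(.makeDiagram(0L, 0, ms, TRUE, ms))
  d <- .distMatrix(x)

  simplices <- list()
  for (dim in 0:min(params@maxDimension + 1L, n - 1L)) {
    subsets <- utils::combn(n, dim + 1L, simplify = FALSE)
    for (v in subsets) {
      s <- if (dim == 0L) 0 else 0.5 * max(d[v, v])
      if (s <= ms) simplices[[length(simplices) + 1L]] <- list(v = v, s = s)
    }
  }
  scales <- vapply(simplices, `[[`, 0, "s")
  dims <- vapply(simplices, function(z) length(z$v) - 1L, 0L)
  lex <- vapply(simplices, function(z)
    paste(formatC(z$v, width = 3, flag = "0"), collapse = ""), "")
  ord <- order(scales, dims, lex)
  simplices <- simplices[ord]
  scales <- scales[ord]
  dims <- dims[ord]
  S <- length(simplices)
  key <- vapply(simplices, function(z) paste(z$v, collapse = ","), "")
  pos <- seq_len(S)
  names(pos) <- key

  # dense boundary matrix over F2
  B <- matrix(FALSE, S, S)
  for (j in seq_len(S)) {
    v <- simplices[[j]]$v
    if (length(v) > 1L)
      for (drop in seq_along(v))
        B[pos[[paste(v[-drop], collapse = ",")]], j] <- TRUE
  }

  lowOf <- function(col) { w <- which(col); if (length(w)) max(w) else 0L }
  ownerOfLow <- integer(S)
  pairs <- matrix(0L, 0L, 2L)
  for (j in seq_len(S)) {
    repeat {
      l <- lowOf(B[, j])
      if (l == 0L || ownerOfLow[l] == 0L) break
      B[, j] <- xor(B[, j], B[, ownerOfLow[l]])
    }
    if (l > 0L) {
      ownerOfLow[l] <- j
      pairs <- rbind(pairs, c(l, j))
    }
  }

  dimv <- integer(); birth <- numeric(); death <- numeric(); capped <- logical()
  pairedBirth <- logical(S); pairedDeath <- logical(S)
  if (nrow(pairs)) {
    pairedBirth[pairs[, 1L]] <- TRUE
    pairedDeath[pairs[, 2L]] <- TRUE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]
      if (dims[i] <= params@maxDimension) {
        dimv <- c(dimv, dims[i]); birth <- c(birth, scales[i])
        death <- c(death, scales[pairs[r, 2L]]); capped <- c(capped, FALSE)
      }
    }
  }
  ess <- which(!pairedBirth & !pairedDeath & dims <= params@maxDimension)
  for (i in ess) {
    dimv <- c(dimv, dims[i]); birth <- c(birth, scales[i])
    death <- c(death, ms); capped <- c(capped, TRUE)
  }
  .makeDiagram(dimv, birth, death, capped, ms)
}

#' @rdname totalLifespan
#' @export
setMethod("totalLifespan", "PersistenceDiagram", function(diagram, dims = 0L) {
  r <- diagram@rows
  keep <- r$dim %in% as.integer(dims)
  if (!any(keep)) return(0)
  sum(r$death[keep] - r$birth[keep])
})

#' @rdname diagramRows
#' @export
setMethod("diagramRows", "PersistenceDiagram", function(diagram) diagram@rows)

#' Write / read a persistence diagram as CSV
#'
#' Columns `dim,birth,death,capped`; floats printed with 17 significant
#' digits so the round trip is lossless.
#'
#' @param diagram a [PersistenceDiagram-class].
#' @param path file path.
#' @return `writeDiagramCsv` returns `path` invisibly; `readDiagramCsv`
#'   returns a [PersistenceDiagram-class].
#' @export
writeDiagramCsv <- function(diagram, path) {
  r <- diagram@rows
  lines <- c(sprintf("# sourceMaxScale=%.17g", diagram@sourceMaxScale),
             "dim,birth,death,capped",
             sprintf("%d,%.17g,%.17g,%s", r$dim, r$birth, r$death,
                     ifelse(r$capped, "TRUE", "FALSE")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDiagramCsv
#' @export
readDiagramCsv <- function(path) {
  lines <- readLines(path)
  ms <- as.numeric(sub("# sourceMaxScale=", "", lines[1L], fixed = TRUE))
  r <- utils::read.csv(text = lines[-1L], stringsAsFactors = FALSE)
  .makeDiagram(r$dim, r$birth, r$death, r$capped, ms)
}

setMethod("show", "PersistenceDiagram", function(object) {
  r <- object@rows
  cat(sprintf("PersistenceDiagram: %d bars (horizon %.6g)\n",
              nrow(r), object@sourceMaxScale))
  for (d in sort(unique(r$dim)))
    cat(sprintf("  dim %d: %d bars, total lifespan %.6g\n", d,
                sum(r$dim == d), totalLifespan(object, d)))
  invisible(NULL)
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in R^%d\n",
              nrow(object@coordinates), ncol(object@coordinates)))
  invisible(NULL)
})
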