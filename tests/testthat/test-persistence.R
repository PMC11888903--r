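# Vietoris-Rips engine: radius convention, fast H0 path, brute-force oracle.

test_that("maxScale is half the cloud diameter, 0 for degenerate clouds", {
  expect_equal(maxScale(PointCloud(rbind(c(0, 0), c(3, 4)))), 2.5)
  expect_equal(maxScale(matrix(c(0, 1, 3), ncol = 1)), 1.5)
  expect_equal(maxScale(matrix(c(7, 7), nrow = 1)), 0)
  expect_error(maxScale(matrix(c(0, NA), ncol = 1)), "finite")
})

test_that("two-point and collinear clouds produce the textbook H0 bars", {
  two <- diagramRows(vrPersistence(rbind(c(0, 0), c(3, 4))))
  expect_equal(two$death, c(2.5, 2.5))
  expect_equal(two$capped, c(FALSE, TRUE))
  expect_equal(two$dim, c(0L, 0L))

  line <- vrPersistence(matrix(c(0, 1, 3), ncol = 1))
  r <- diagramRows(line)
  h0 <- r[r$dim == 0L, ]
  expect_equal(h0$death, c(0.5, 1.0, 1.5))
  expect_equal(sum(h0$capped), 1L)
  # no persistent loop on a line (a zero-lifespan pair may be emitted)
  h1 <- r[r$dim == 1L, ]
  expect_true(all(h1$death - h1$birth < 1e-12 & !h1$capped))
})

test_that("degenerate clouds are legal: empty diagram, single capped bar", {
  expect_equal(nrow(diagramRows(vrPersistence(matrix(0, 0, 2)))), 0L)
  one <- diagramRows(vrPersistence(matrix(c(7, 7), nrow = 1)))
  expect_equal(one, data.frame(dim = 0L, birth = 0, death = 0, capped = TRUE))
  expect_error(FiltrationParams(2L), "unsupported")
})

test_that("unit square: three merges plus one loop born 0.5 dead sqrt(2)/2", {
  d <- vrPersistence(unitSquare())
  r <- nonzeroBars(d)
  expect_equal(r[r$dim == 0L, "death"],
               c(0.5, 0.5, 0.5, sqrt(2) / 2), tolerance = 1e-12)
  h1 <- r[r$dim == 1L, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 0.5, tolerance = 1e-12)
  expect_equal(h1$death, sqrt(2) / 2, tolerance = 1e-12)
  expect_false(h1$capped)
})

test_that("brute-force oracle: clique complex kills triangle loops at birth", {
  r <- diagramRows(bruteForcePersistence(equilateralTriangle()))
  h0 <- r[r$dim == 0L, ]
  expect_equal(h0$death, c(0.5, 0.5, 0.5))
  expect_equal(sum(h0$capped), 1L)
  h1 <- r[r$dim == 1L, ]
  expect_true(all(h1$death == h1$birth))
  expect_error(bruteForcePersistence(randomCloud(11)), "10 points")
  one <- diagramRows(bruteForcePersistence(matrix(1, 1, 2)))
  expect_equal(one, data.frame(dim = 0L, birth = 0, death = 0, capped = TRUE))
})

test_that("totalLifespan sums death - birth over the selected dimensions", {
  empty <- vrPersistence(matrix(0, 0, 2))
  expect_equal(totalLifespan(empty, 0L), 0)
  two <- vrPersistence(rbind(c(0, 0), c(3, 4)))
  expect_equal(totalLifespan(two, 0L), 5)
  sq <- bruteForcePersistence(unitSquare())
  expect_equal(totalLifespan(sq, c(0L, 1L)),
               1.5 + sqrt(2) / 2 + (sqrt(2) / 2 - 0.5), tolerance = 1e-12)
})

test_that("MST fast path reproduces the engine's dimension-0 bars", {
  line <- diagramRows(h0PersistenceMST(matrix(c(0, 1, 3), ncol = 1)))
  expect_equal(line$death, c(0.5, 1.0, 1.5))
  two <- diagramRows(h0PersistenceMST(rbind(c(0, 0), c(3, 4))))
  expect_equal(two$death, c(2.5, 2.5))
  for (seed in 1:6) {
    x <- randomCloud(30, m = 3L, seed = seed)
    a <- diagramRows(h0PersistenceMST(x))
    b <- diagramRows(vrPersistence(x, FiltrationParams(0L)))
    expect_equal(a$death, b$death[b$dim == 0L], tolerance = 1e-12)
    expect_equal(sum(a$capped), 1L)
  }
})

test_that("scaling all coordinates by c scales every birth and death by c", {
  x <- randomCloud(12, m = 3L, seed = 9)
  for (c in c(0.3, 7)) {
    a <- diagramRows(vrPersistence(x))
    b <- diagramRows(vrPersistence(c * x))
    expect_equal(b$birth, c * a$birth, tolerance = 1e-10)
    expect_equal(b$death, c * a$death, tolerance = 1e-10)
  }
})

test_that("auto horizon: deaths bounded, exactly one capped component", {
  for (seed in 1:8) {
    n <- sample(3:25, 1)
    x <- randomCloud(n, m = 2L, seed = seed)
    d <- vrPersistence(x)
    r <- diagramRows(d)
    expect_true(all(r$death <= d@sourceMaxScale + 1e-12))
    expect_equal(sum(r$capped & r$dim == 0L), 1L)
    expect_equal(sum(r$dim == 0L), n)  # one bar per point
  }
})

test_that("truncated horizon caps unfinished components and loops", {
  x <- diagramRows(vrPersistence(matrix(c(0, 1, 10), ncol = 1),
                                 FiltrationParams(0L, maxScale = 1)))
  expect_equal(sum(x$capped), 2L)  # two components never merge by eps = 1
  circ <- makeShapeCloud("circle", 40, seed = 2)
  d <- diagramRows(vrPersistence(circ, FiltrationParams(1L, maxScale = 0.5)))
  h1 <- d[d$dim == 1L & d$capped, ]
  expect_gte(nrow(h1), 1L)  # the circle's loop outlives the horizon
})

test_that("a dense noiseless circle has one dominant loop", {
  circ <- makeShapeCloud("circle", 100, noiseSd = 0, seed = 3)
  r <- diagramRows(vrPersistence(circ))
  h1 <- r[r$dim == 1L, ]
  life <- sort(h1$death - h1$birth, decreasing = TRUE)
  expect_gte(length(life), 1L)
  runner <- if (length(life) > 1L) life[2L] else 0
  expect_gt(life[1L], 5 * max(runner, 1e-9))
})

test_that("a torus sample retains a long loop under a truncated horizon", {
  cloud <- makeShapeCloud("torus", 250, noiseSd = 0.01, seed = 4)
  d <- vrPersistence(cloud, FiltrationParams(1L, maxScale = 0.75))
  r <- diagramRows(d)
  h1 <- r[r$dim == 1L, ]
  expect_gt(max(h1$death - h1$birth), 0.3)
})

test_that("diagram CSV round-trips losslessly", {
  d <- vrPersistence(randomCloud(9, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDiagramCsv(d, path)
  d2 <- readDiagramCsv(path)
  expect_identical(diagramRows(d), diagramRows(d2))
  expect_identical(d@sourceMaxScale, d2@sourceMaxScale)
})
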