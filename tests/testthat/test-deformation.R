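test_that("grid construction counts match hand-derived cases", {
  g1 <- makeGrid(rectContour(1, 1), spacing = 1, margin = 0)
  expect_equal(g1@dims, c(2L, 2L))
  expect_equal(g1@origin, c(0, 0))
  g2 <- makeGrid(rectContour(10, 5), spacing = 1, margin = 1)
  expect_equal(g2@dims, c(13L, 8L))
  expect_equal(g2@origin, c(-1, -1))
  expect_equal(nrow(gridPoints(g2)), 13L * 8L)
})

test_that("identity and translation fields are exact", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  idf <- evaluateField(tpsSolve(coords(blob), coords(blob)), g, blob)
  expect_lt(max(abs(idf@dx)), 1e-7)
  expect_lt(max(abs(idf@dy)), 1e-7)
  t <- c(2, -3)
  trf <- evaluateField(translationTransform(t, at = c(8, 8)), g, blob)
  expect_equal(max(abs(trf@dx - t[1L])), 0, tolerance = 1e-7)
  expect_equal(max(abs(trf@dy - t[2L])), 0, tolerance = 1e-7)
})

test_that("field evaluation matches the independent kernel oracle", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  f <- smoothWarpTransform(19, sd = 1)
  fld <- evaluateField(f, g, blob)
  set.seed(2)
  pick <- sample.int(prod(g@dims), 10L)
  gp <- gridPoints(g)[pick, , drop = FALSE]
  expected <- oracleTpsEval(f, gp) - gp
  got <- cbind(as.vector(fld@dx)[pick], as.vector(fld@dy)[pick])
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("composition equals brute-force nested evaluation", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  f1 <- smoothWarpTransform(23, sd = 1)
  f2 <- smoothWarpTransform(24, sd = 1)
  comp <- concatenateTransforms(list(f1, f2), g, blob)
  gp <- gridPoints(g)
  brute <- oracleTpsEval(f2, oracleTpsEval(f1, gp)) - gp
  expect_equal(cbind(as.vector(comp@dx), as.vector(comp@dy)), brute,
               tolerance = 1e-9)
})

test_that("translations compose additively and singletons match evaluateField", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  t1 <- c(1.5, 2); t2 <- c(-0.5, 3)
  comp <- concatenateTransforms(list(translationTransform(t1),
                                     translationTransform(t2)), g, blob)
  expect_equal(max(abs(comp@dx - (t1[1L] + t2[1L]))), 0, tolerance = 1e-9)
  expect_equal(max(abs(comp@dy - (t1[2L] + t2[2L]))), 0, tolerance = 1e-9)
  f <- smoothWarpTransform(29, sd = 1)
  one <- concatenateTransforms(list(f), g, blob)
  direct <- evaluateField(f, g, blob)
  expect_identical(one@dx, direct@dx)
  expect_identical(one@dy, direct@dy)
  expect_identical(one@inside, direct@inside)
  # empty list gives the zero field
  z <- concatenateTransforms(list(), g, blob)
  expect_true(all(z@dx == 0) && all(z@dy == 0))
})

test_that("composition is associative", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  fs <- lapply(c(31, 32, 33), smoothWarpTransform, sd = 0.8)
  a <- concatenateTransforms(fs, g, blob)
  # (f1, f2) then f3 by pushing the composed positions through f3
  gp <- gridPoints(g)
  p12 <- gp + cbind(as.vector(concatenateTransforms(fs[1:2], g, blob)@dx),
                    as.vector(concatenateTransforms(fs[1:2], g, blob)@dy))
  p123 <- transformPoints(fs[[3L]], p12)
  expect_equal(cbind(as.vector(a@dx), as.vector(a@dy)), p123 - gp,
               tolerance = 1e-9)
})

test_that("the inside mask is margin-invariant and boundary-inclusive", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  f <- translationTransform(c(1, 1))
  g0 <- makeGrid(blob, margin = 0)
  g4 <- makeGrid(blob, margin = 4)
  m0 <- evaluateField(f, g0, blob)
  m4 <- evaluateField(f, g4, blob)
  in0 <- as.data.frame(m0); in4 <- as.data.frame(m4)
  key <- function(df) paste(df$x_mm, df$y_mm)
  shared <- intersect(key(in0), key(in4))
  expect_identical(in0$inside[match(shared, key(in0))],
                   in4$inside[match(shared, key(in4))])
  # contour vertices themselves count as inside
  sq <- rectContour(4, 4, at = c(1, 1))
  gsq <- makeGrid(sq, margin = 1)
  fld <- evaluateField(f, gsq, sq)
  df <- as.data.frame(fld)
  corner <- df$x_mm == 1 & df$y_mm == 1
  expect_true(df$inside[corner])
})

test_that("inside mask agrees with an independent point-in-polygon oracle", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob, margin = 3)
  fld <- evaluateField(translationTransform(c(0, 1)), g, blob)
  gp <- gridPoints(g)
  oracle <- mgcv::in.out(rbind(coords(blob), coords(blob)[1L, ]), gp)
  got <- as.vector(fld@inside)
  # allow disagreement only for points essentially on the boundary
  disag <- which(got != oracle)
  if (length(disag)) {
    d <- oracleDistToPolygon(gp[disag, , drop = FALSE], coords(blob))
    expect_lt(max(d), 1e-6)
  } else succeed()
})

test_that("field CSV export round-trips through its data.frame", {
  blob <- blobContour(radius = 6, at = c(8, 8))
  g <- makeGrid(blob)
  fld <- evaluateField(translationTransform(c(1, 2)), g, blob)
  path <- withr::local_tempfile(fileext = ".csv")
  writeDeformationField(fld, path)
  back <- utils::read.csv(path)
  expect_equal(back, as.data.frame(fld), tolerance = 1e-9)
})
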