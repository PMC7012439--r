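test_that("registering a set onto itself recovers the identity", {
  us <- toUnitBox(blobContour(radius = 12))$points
  res <- annealRegister(us, us)
  V <- coords(us)
  expect_lt(max(abs(transformPoints(res$transform, V) - V)), 1e-4)
  # no point ends up assigned to an outlier bin
  expect_identical(tail(res$diagnostics$nOutlierAssigned, 1L), 0L)
})

test_that("a mild affine warp is recovered to 1e-2 in the unit box", {
  b <- coords(blobContour(radius = 12))
  tgtMm <- b %*% rotationMatrix(15) * 1.05 + 2
  sc <- unitBoxScaling(list(pointSet(b), pointSet(tgtMm)))
  us <- coords(toUnitBox(pointSet(b), sc)$points)
  ut <- coords(toUnitBox(pointSet(tgtMm), sc)$points)
  res <- annealRegister(pointSet(us), pointSet(ut))
  expect_lt(max(abs(transformPoints(res$transform, us) - ut)), 1e-2)
})

test_that("a smooth synthetic TPS warp is recovered to 1e-2 in the unit box", {
  us <- coords(toUnitBox(blobContour(radius = 12))$points)
  f0 <- smoothWarpTransform(7, sd = 0.035, box = c(0, 1))
  ut <- transformPoints(f0, us)
  res <- annealRegister(pointSet(us), pointSet(ut))
  expect_lt(max(abs(transformPoints(res$transform, us) - ut)), 1e-2)
  # rigidity is annealed: the accepted transform bends more as T falls
  bend <- res$diagnostics$bending
  expect_lt(bend[1L], tail(bend, 1L))
})

test_that("outliers in both sets do not corrupt the inlier registration", {
  set.seed(11)
  n <- 60L
  blob <- coords(blobContour(radius = 14, n = n, at = c(20, 20)))
  f0 <- smoothWarpTransform(77, sd = 1.2, box = c(0, 40))
  tgtTrue <- transformPoints(f0, blob)
  nOut <- round(0.3 * n)
  # spurious points offset outward on the source side and inward on the
  # target side, so no spurious point has a counterpart in the other set
  spur <- function(base, sgn) {
    at <- sample.int(n, nOut)
    dir <- base[at, ] - matrix(colMeans(base), nOut, 2L, byrow = TRUE)
    dir <- dir / sqrt(rowSums(dir^2))
    base[at, ] + sgn * dir * runif(nOut, 5, 9)
  }
  S <- rbind(blob, spur(blob, +1))
  X <- rbind(tgtTrue, spur(tgtTrue, -1))
  sc <- unitBoxScaling(list(pointSet(S), pointSet(X)))
  res <- annealRegister(toUnitBox(pointSet(S), sc)$points,
                        toUnitBox(pointSet(X), sc)$points)
  tfMm <- rescaleTransform(res$transform, sc)
  # the mapped inlier contour must land on the true warped contour
  err <- registrationError(transformPoints(tfMm, pointSet(blob)),
                           pointSet(tgtTrue))
  expect_lt(err, 1)
  # every spurious point, and only spurious points, ends up with its
  # strongest assignment in an outlier bin
  expect_identical(tail(res$diagnostics$nOutlierAssigned, 1L),
                   as.integer(2 * nOut))
  # spurious source points are starved of inner correspondence mass
  m <- res$correspondence
  w <- colSums(m[-1L, -1L, drop = FALSE])
  expect_lt(mean(w[n + seq_len(nOut)]), mean(w[seq_len(n)]))
})

test_that("registerPair recovers a known translation at every contour point", {
  th <- seq(0, 2 * pi, length.out = 73L)[-73L]
  src <- pointSet(cbind(15 * cos(th), 10 * sin(th)))
  tgt <- pointSet(cbind(15 * cos(th), 5 + 10 * sin(th)))
  reg <- registerPair(src, tgt)
  expect_s4_class(reg, "PairRegistration")
  expect_identical(reg@status, "ok")
  d <- transformPoints(reg@transform, coords(src)) - coords(src)
  expect_lt(max(abs(sweep(d, 2L, c(0, 5)))), 0.1)
  # identical contours: transform within 0.01 mm of the identity
  reg0 <- registerPair(src, src)
  d0 <- transformPoints(reg0@transform, coords(src)) - coords(src)
  expect_lt(max(abs(d0)), 0.01)
})

test_that("the matcher is fully deterministic", {
  us <- toUnitBox(blobContour(radius = 10))$points
  f0 <- smoothWarpTransform(5, sd = 1, box = c(-15, 15))
  ut <- transformPoints(f0, us)
  r1 <- annealRegister(us, ut)
  r2 <- annealRegister(us, ut)
  expect_identical(r1$transform@warpCoeffs, r2$transform@warpCoeffs)
  expect_identical(r1$correspondence, r2$correspondence)
  expect_identical(r1$diagnostics, r2$diagnostics)
})

test_that("the annealing trace exposes residual and outlier mass", {
  us <- toUnitBox(blobContour(radius = 10))$points
  res <- annealRegister(us, us)
  tr <- res$diagnostics
  expect_true(all(c("iter", "T", "lambda", "residual", "outlierMass",
                    "bending") %in% names(tr)))
  expect_true(all(diff(tr$T) < 0))        # strictly cooling
  expect_true(all(tr$residual >= 0))
})
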