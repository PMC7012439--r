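test_that("single-vector decompositions match hand computation", {
  fr <- anatomicalFrame()
  expect_equal(decomposeVector(c(0, 5), fr),
               c(superior = 5, inferior = 0, anterior = 0, posterior = 0))
  expect_equal(decomposeVector(c(0, 0), fr),
               c(superior = 0, inferior = 0, anterior = 0, posterior = 0))
  expect_equal(decomposeVector(c(3, -4), fr),
               c(superior = 0, inferior = 4, anterior = 3, posterior = 0))
})

test_that("decomposition algebra holds exactly for random vectors", {
  set.seed(17)
  fr <- anatomicalFrame()
  flipped <- anatomicalFrame(si = c(0, -1), ap = c(1, 0))
  v <- matrix(rnorm(200, sd = 8), ncol = 2L)
  d <- decomposeVector(v, fr)
  s <- v %*% fr@si
  expect_identical(d[, "superior"] + d[, "inferior"], abs(as.vector(s)))
  expect_identical(d[, "superior"] * d[, "inferior"], rep(0, nrow(v)))
  expect_identical(d[, "anterior"] * d[, "posterior"], rep(0, nrow(v)))
  # reversing the SI axis swaps superior and inferior, AP untouched
  df <- decomposeVector(v, flipped)
  expect_identical(df[, "superior"], d[, "inferior"])
  expect_identical(df[, "inferior"], d[, "superior"])
  expect_identical(df[, "anterior"], d[, "anterior"])
})

test_that("anatomical frames must be orthonormal", {
  expect_error(new("AnatomicalFrame", si = c(0, 2), ap = c(1, 0)), "unit")
  expect_error(new("AnatomicalFrame", si = c(0, 1), ap = c(0, 1)),
               "orthogonal")
  # constructor normalises
  fr <- anatomicalFrame(si = c(0, 10), ap = c(3, 0))
  expect_equal(fr@si, c(0, 1))
  expect_equal(fr@ap, c(1, 0))
})

test_that("roiMotion averages rectified components over the inside mask", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  up5 <- evaluateField(translationTransform(c(0, 5)), g, blob)
  expect_equal(roiMotion(up5),
               c(superior = 5, inferior = 0, anterior = 0, posterior = 0),
               tolerance = 1e-9)
  # zero field
  z <- concatenateTransforms(list(), g, blob)
  expect_equal(unname(roiMotion(z)), rep(0, 4))
  # half the mask up 4, half down 4: per-point rectification averages to 2/2
  half <- up5
  dy <- half@dy
  dy[] <- 4
  gp <- gridPoints(g)
  dy[matrix(gp[, 1L] > 10, nrow(dy), ncol(dy))] <- -4
  half@dy <- dy
  half@dx <- dy * 0
  nIn <- sum(half@inside)
  nUp <- sum(half@inside & dy > 0)
  mot <- roiMotion(half)
  expect_equal(mot[["superior"]], 4 * nUp / nIn)
  expect_equal(mot[["inferior"]], 4 * (nIn - nUp) / nIn)
  # a uniform field is mask-independent: equals the plain decomposition
  expect_equal(roiMotion(up5), decomposeVector(c(0, 5)), tolerance = 1e-9)
})

test_that("an empty inside mask is an error", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  g <- makeGrid(blob)
  f <- evaluateField(translationTransform(c(0, 1)), g, blob)
  f@inside[] <- FALSE
  expect_error(roiMotion(f), "inside")
})

test_that("per-step translations accumulate from the initial frame", {
  sq <- rectContour(8, 8)
  step <- c(0, 2)
  framesList <- lapply(0:3, function(k)
    pointSet(coords(sq) + matrix(k * step, 4L, 2L, byrow = TRUE)))
  seq <- contourSequence("roi", framesList)
  transforms <- lapply(1:3, function(k) translationTransform(step))
  tab <- motionTimecourse(seq, transforms)
  pf <- perFrameMotion(tab)
  expect_equal(pf$superior, c(0, 2, 4, 6), tolerance = 1e-7)
  expect_equal(pf$inferior, rep(0, 4), tolerance = 1e-7)
  expect_equal(motionSummary(tab)[["superior"]], 6, tolerance = 1e-7)
  # summary dominates per-frame values, magnitudes non-negative
  expect_true(all(as.matrix(pf[, -1L]) >= 0))
  expect_true(all(motionSummary(tab) >=
                    apply(as.matrix(pf[, -1L]), 2L, max) - 1e-12))
})

test_that("all-identity transforms give an all-zero motion table", {
  blob <- blobContour(radius = 8, at = c(10, 10))
  framesList <- list(blob, blob, blob)
  seq <- contourSequence("static", framesList)
  id <- tpsSolve(coords(rectContour(4, 4)), coords(rectContour(4, 4)))
  tab <- motionTimecourse(seq, list(id, id))
  expect_lt(max(as.matrix(perFrameMotion(tab)[, -1L])), 1e-7)
})

test_that("the ground-truth peak frame is identified from the time course", {
  sp <- syntheticSpec("larynx", shape = "ellipse",
                      shapeParams = list(a = 14, b = 11),
                      amplitudes = c(superior = 12, inferior = 6),
                      nFrames = 20L, peakFrame = 15L, seed = 4L)
  gen <- generateSequence(sp)
  pf <- perFrameMotion(gen$truth)
  si <- pf$superior + pf$inferior
  expect_equal(which.max(si), 15L)
})

test_that("motion table validity enforces its invariants", {
  bad <- data.frame(frame = 1:2, superior = c(1, 0), inferior = 0,
                    anterior = 0, posterior = 0)
  expect_error(motionTable("x", bad), "first contoured frame")
  good <- data.frame(frame = 1:2, superior = c(0, 3), inferior = 0,
                     anterior = 0, posterior = 0)
  expect_equal(motionSummary(motionTable("x", good))[["superior"]], 3)
})
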