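# O(n^2) segment-intersection simple-polygon check (test-side oracle)
isSimplePolygon <- function(p) {
  n <- nrow(p)
  segs <- cbind(p, p[c(2:n, 1L), ])
  crosses <- function(a1, a2, b1, b2) {
    d <- function(u, v, w) (v[1L] - u[1L]) * (w[2L] - u[2L]) -
      (v[2L] - u[2L]) * (w[1L] - u[1L])
    (d(a1, a2, b1) * d(a1, a2, b2) < 0) && (d(b1, b2, a1) * d(b1, b2, a2) < 0)
  }
  for (i in seq_len(n - 2L)) for (j in (i + 2L):n) {
    if (i == 1L && j == n) next  # adjacent through the wrap
    if (crosses(segs[i, 1:2], segs[i, 3:4], segs[j, 1:2], segs[j, 3:4]))
      return(FALSE)
  }
  TRUE
}

test_that("zero amplitude and zero noise give identical frames and zero truth", {
  sp <- syntheticSpec("static", amplitudes = c(superior = 0), nFrames = 5L)
  gen <- generateSequence(sp)
  fr <- frames(gen$sequence)
  for (k in 2:5) expect_identical(coords(fr[[k]]), coords(fr[[1L]]))
  expect_true(all(as.matrix(perFrameMotion(gen$truth)[, -1L]) == 0))
})

test_that("a pure translation ramp has its amplitudes as exact truth", {
  sp <- syntheticSpec("ramp", amplitudes = c(superior = 10), nFrames = 9L,
                      peakFrame = 5L)
  gen <- generateSequence(sp)
  expect_equal(motionSummary(gen$truth)[["superior"]], 10)
  expect_equal(motionSummary(gen$truth)[["inferior"]], 0)
  # frame 5 contour is the base contour shifted by exactly (0, 10)
  fr <- frames(gen$sequence)
  expect_equal(coords(fr[[5L]]) - coords(fr[[1L]]),
               matrix(c(0, 10), nPoints(fr[[1L]]), 2L, byrow = TRUE))
  # with a rebound direction, the inferior amplitude is reached too
  sp2 <- syntheticSpec("updown", nFrames = 11L, peakFrame = 6L,
                       amplitudes = c(superior = 8, inferior = 5,
                                      anterior = 2, posterior = 1))
  tr2 <- generateSequence(sp2)$truth
  expect_equal(unname(motionSummary(tr2)), c(8, 5, 2, 1), tolerance = 1e-9)
})

test_that("generation is bit-identical per seed and differs across seeds", {
  sp0 <- syntheticSpec("larynx", noiseSd = 0.3, warpSd = 1, seed = 0L)
  a <- generateSequence(sp0)
  b <- generateSequence(sp0)
  expect_identical(lapply(frames(a$sequence), coords),
                   lapply(frames(b$sequence), coords))
  sp1 <- syntheticSpec("larynx", noiseSd = 0.3, warpSd = 1, seed = 1L)
  c <- generateSequence(sp1)
  expect_false(identical(coords(frames(a$sequence)[[2L]]),
                         coords(frames(c$sequence)[[2L]])))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- rnorm(1)
  set.seed(99)
  invisible(generateSequence(syntheticSpec("r", noiseSd = 0.2, seed = 5L)))
  expect_identical(rnorm(1), x1)
})

test_that("default scene shapes stay simple polygons under moderate noise", {
  specs <- defaultSwallowScene(seed = 2L, nFrames = 6L, noiseSd = 0.5)
  expect_length(specs, 7L)
  expect_setequal(names(specs),
                  c("pharyngeal_constrictor", "epiglottis", "base_of_tongue",
                    "geniohyoid", "hyoid", "soft_palate", "larynx"))
  for (nm in c("pharyngeal_constrictor", "soft_palate", "larynx")) {
    gen <- generateSequence(specs[[nm]])
    for (k in c(1L, 4L))
      expect_true(isSimplePolygon(coords(frames(gen$sequence)[[k]])),
                  label = sprintf("%s frame %d is simple", nm, k))
  }
  # the pharyngeal-constrictor stand-in is narrow elongate (aspect >= 8)
  pcSpec <- specs$pharyngeal_constrictor
  expect_gte(pcSpec@shapeParams$length / pcSpec@shapeParams$width, 8)
  pc <- coords(frames(generateSequence(pcSpec)$sequence)[[1L]])
  ext <- apply(pc, 2L, function(z) diff(range(z)))
  expect_gte(max(ext) / min(ext), 5)  # bbox ratio, widened by the bow
})

test_that("spurious points are inserted at the requested rate", {
  sp <- syntheticSpec("noisy", outlierFraction = 0.2, nFrames = 3L,
                      shapeParams = list(a = 15, b = 10), seed = 8L)
  clean <- syntheticSpec("clean", nFrames = 3L,
                         shapeParams = list(a = 15, b = 10), seed = 8L)
  nNoisy <- nPoints(frames(generateSequence(sp)$sequence)[[1L]])
  nClean <- nPoints(frames(generateSequence(clean)$sequence)[[1L]])
  expect_equal(nNoisy, nClean + floor(0.2 * nClean))
})

test_that("the registration-case generator is seeded and family-aware", {
  a <- syntheticRegistrationCase(3L, family = "smooth")
  b <- syntheticRegistrationCase(3L, family = "smooth")
  expect_identical(a@shapeParams, b@shapeParams)
  expect_identical(a@amplitudes, b@amplitudes)
  expect_true(a@shape %in% c("ellipse", "blob"))
  h <- syntheticRegistrationCase(3L, family = "elongate")
  expect_true(h@shape %in% c("crescent", "band"))
  expect_equal(a@nFrames, 2L)
  # translation magnitude respects the cap
  mag <- sqrt(sum((a@amplitudes[c("anterior", "superior")] -
                     a@amplitudes[c("posterior", "inferior")])^2))
  expect_lte(mag, 15)
})

test_that("spec validity catches inconsistent recipes", {
  expect_error(syntheticSpec(shape = "hexagon"), "shape")
  expect_error(syntheticSpec(nFrames = 1L), "nFrames|peakFrame")
  expect_error(syntheticSpec(amplitudes = c(up = 3)), "directions")
  expect_error(syntheticSpec(outlierFraction = 1), "outlierFraction")
})
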