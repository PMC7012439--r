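## Parametric base shapes for synthetic swallowing ROIs. All return a
## counter-clockwise closed polygon (matrix, mm) centred at the origin with
## vertex spacing of roughly 1 mm.

.shapeEllipse <- function(a = 15, b = 10) {
  n <- max(24L, round(pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(a * cos(th), b * sin(th))
}

.shapeBlob <- function(radius = 12, harmonics = c(0.12, 0.08, 0.05),
                       phases = c(0.7, 2.1, 4.0)) {
  phases <- rep_len(phases, length(harmonics))
  n <- max(36L, round(2 * pi * radius))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- radius * (1 + Reduce(`+`, Map(function(k, a, p) a * cos(k * th + p),
                                     seq_along(harmonics) + 1L,
                                     harmonics, phases)))
  cbind(r * cos(th), r * sin(th))
}

## crescent: circular-arc centreline of radius `radius` spanning `span`
## radians, with half-width tapering sinusoidally towards the tips; the tip
## floor keeps the two walls separated under delineation-scale jitter
.shapeCrescent <- function(radius = 18, width = 6, span = 3.6) {
  nArc <- max(18L, round(radius * span))
  th <- seq(pi / 2 - span / 2, pi / 2 + span / 2, length.out = nArc)
  u <- seq(0, 1, length.out = nArc)
  hw <- pmax(0.15 * width, (width / 2) * sin(pi * u))
  outer <- cbind((radius + hw) * cos(th), (radius + hw) * sin(th))
  inner <- cbind((radius - hw) * cos(rev(th)), (radius - hw) * sin(rev(th)))
  ctr <- c(0, radius * mean(sin(th)) * 0.9)
  sweep(rbind(outer, inner), 2L, ctr)
}

## band: narrow elongate stadium (vertical long axis), optionally bowed; the
## pharyngeal-constrictor-like shape with aspect = length / width
.shapeBand <- function(length = 40, width = 4, bow = 0) {
  hw <- width / 2
  body <- length - width          # straight part, caps add width
  ny <- max(8L, round(body))
  ys <- seq(-body / 2, body / 2, length.out = ny)
  bowx <- function(y) bow * cos(pi * y / length)
  right <- cbind(hw + bowx(ys), ys)
  left <- cbind(-hw + bowx(rev(ys)), rev(ys))
  nCap <- max(4L, round(pi * hw))
  thTop <- seq(0, pi, length.out = nCap + 2L)[2:(nCap + 1L)]
  top <- cbind(hw * cos(thTop) + bowx(body / 2), body / 2 + hw * sin(thTop))
  thBot <- seq(pi, 2 * pi, length.out = nCap + 2L)[2:(nCap + 1L)]
  bottom <- cbind(hw * cos(thBot) + bowx(-body / 2),
                  -body / 2 + hw * sin(thBot))
  rbind(right, top, left, bottom)
}

## outward unit normals of a closed polygon (central differences)
.contourNormals <- function(pts) {
  n <- nrow(pts)
  tangent <- pts[c(2:n, 1L), ] - pts[c(n, 1:(n - 1L)), ]
  nrm <- cbind(tangent[, 2L], -tangent[, 1L])
  nrm / sqrt(rowSums(nrm^2))
}

.baseShape <- function(shape, params) {
  fun <- switch(shape, ellipse = .shapeEllipse, blob = .shapeBlob,
                crescent = .shapeCrescent, band = .shapeBand,
                stop("unknown shape: ", shape))
  do.call(fun, params)
}

## Scalar swallow profile s(k) in [-1, 1]: 0 at the first frame, +1 at the
## peak frame (primary excursion), -1 at the rebound frame when a return
## overshoot is modelled, 0 again at the end.
.motionProfile <- function(n, peak, rebound = TRUE) {
  s <- numeric(n)
  k <- seq_len(n)
  up <- k <= peak
  s[up] <- 0.5 * (1 - cos(pi * (k[up] - 1) / max(1, peak - 1)))
  if (peak < n) {
    if (rebound) {
      q <- min(n, peak + max(1L, round((n - peak) / 2)))
      mid <- k > peak & k <= q
      s[mid] <- cos(pi * (k[mid] - peak) / (q - peak))
      late <- k > q
      if (any(late))
        s[late] <- -cos(pi * (k[late] - q) / (2 * (n - q)))
    } else {
      down <- k > peak
      s[down] <- 0.5 * (1 + cos(pi * (k[down] - peak) / (n - peak)))
    }
  }
  s
}

## per-frame translation vectors (n x 2) implied by the directional
## amplitude model: +excursion towards (anterior, superior) amplitudes,
## rebound towards (posterior, inferior) amplitudes
.translationProfile <- function(amplitudes, n, peak) {
  vPlus <- c(amplitudes[["anterior"]], amplitudes[["superior"]])
  vMinus <- c(amplitudes[["posterior"]], amplitudes[["inferior"]])
  s <- .motionProfile(n, peak, rebound = any(vMinus > 0))
  t(vapply(s, function(si) if (si >= 0) si * vPlus else si * vMinus,
           numeric(2)))
}

#' Generate a synthetic contour sequence with known ground truth
#'
#' Builds one ROI's cine sequence from a [SyntheticSpec-class]: the base
#' shape is carried through the frames by a smooth time-varying displacement
#' (a directional translation rising to the peak frame and optionally
#' rebounding past rest, plus a low-order TPS perturbation scaled by the
#' same activation), then per-point Gaussian jitter along the local contour
#' normal (delineation uncertainty acts across the boundary; tangential
#' jitter is unobservable along a contour) and optional spurious points are
#' added. The ground-truth motion table is computed analytically
#' from the noise-free motion model on the same grid the estimation pipeline
#' uses, so estimated and true motion are directly comparable.
#'
#' Shape parameters (\code{shapeParams}, mm): \code{ellipse}: \code{a},
#' \code{b} semi-axes; \code{blob}: \code{radius}, \code{harmonics},
#' \code{phases}; \code{crescent}: \code{radius}, \code{width}, \code{span};
#' \code{band}: \code{length}, \code{width}, \code{bow}.
#'
#' @param spec a [SyntheticSpec-class].
#' @param gridSpacing,margin grid used for the ground-truth motion table.
#' @return A list with elements \code{sequence} (a
#'   [ContourSequence-class]), \code{truth} (the ground-truth
#'   [MotionTable-class]), \code{truthDisplacement} (function
#'   \code{(k, points)} returning the true displacement vectors at frame k),
#'   and \code{grid} (the [GridDefinition-class] used for the truth table).
#'   Identical seeds give bit-identical output.
#' @examples
#' gen <- generateSequence(syntheticSpec("larynx", nFrames = 8,
#'                                       amplitudes = c(superior = 10)))
#' motionSummary(gen$truth)
#' @export
generateSequence <- function(spec, gridSpacing = 1, margin = 2) {
  stopifnot(is(spec, "SyntheticSpec"))
  .withSeed(spec@seed, {
    base <- sweep(.baseShape(spec@shape, spec@shapeParams), 2L,
                  spec@center, "+")
    n <- spec@nFrames
    trans <- .translationProfile(spec@amplitudes, n, spec@peakFrame)
    act <- abs(.motionProfile(n, spec@peakFrame,
                              rebound = any(spec@amplitudes[c("inferior",
                                                              "posterior")] > 0)))

    warpFun <- NULL
    if (spec@warpSd > 0) {
      lo <- apply(base, 2L, min) - 5
      hi <- apply(base, 2L, max) + 5
      ctrl <- as.matrix(expand.grid(x = seq(lo[1L], hi[1L], length.out = 4),
                                    y = seq(lo[2L], hi[2L], length.out = 4)))
      dimnames(ctrl) <- NULL
      tgt <- ctrl + matrix(rnorm(length(ctrl), sd = spec@warpSd),
                           ncol = 2L)
      wtf <- tpsSolve(ctrl, tgt, lam = 1)  # mild smoothing keeps it gentle
      warpFun <- function(p) transformPoints(wtf, p) - p
    }

    truthDisp <- function(k, pts) {
      pts <- .asCoordMatrix(pts)
      d <- matrix(trans[k, ], nrow(pts), 2L, byrow = TRUE)
      if (!is.null(warpFun)) d <- d + act[k] * warpFun(pts)
      d
    }

    frames <- vector("list", n)
    for (k in seq_len(n)) {
      pts <- base + truthDisp(k, base)
      if (spec@noiseSd > 0)
        pts <- pts + .contourNormals(pts) * rnorm(nrow(pts),
                                                  sd = spec@noiseSd)
      nOut <- floor(spec@outlierFraction * nrow(pts))
      if (nOut > 0) {
        at <- sort(sample.int(nrow(pts), nOut))
        spur <- pts[at, , drop = FALSE] +
          matrix(runif(2 * nOut, 2, 6) * sign(runif(2 * nOut, -1, 1)),
                 ncol = 2L)
        out <- matrix(NA_real_, nrow(pts) + nOut, 2L)
        pos <- at + seq_len(nOut)  # insert after the sampled vertices
        out[pos, ] <- spur
        out[-pos, ] <- pts
        pts <- out
      }
      frames[[k]] <- pointSet(pts)
    }
    seq <- contourSequence(spec@roi, frames, pixelSpacing = spec@pixelSpacing,
                           frameInterval = spec@frameInterval)

    grid <- makeGrid(pointSet(base), spacing = gridSpacing, margin = margin)
    g <- gridPoints(grid)
    inside <- .insidePolygon(g, base)
    fr <- anatomicalFrame()
    mags <- matrix(0, n, 4L, dimnames = list(NULL, .DIRECTIONS))
    for (k in 2:n)
      mags[k, ] <- colMeans(decomposeVector(
        truthDisp(k, g)[inside, , drop = FALSE], fr))
    truth <- motionTable(spec@roi, data.frame(frame = seq_len(n), mags))

    list(sequence = seq, truth = truth, truthDisplacement = truthDisp,
         grid = grid)
  })
}

#' The default 7-ROI synthetic swallowing scene
#'
#' One [SyntheticSpec-class] per swallowing structure (pharyngeal
#' constrictor, epiglottis, base of tongue, geniohyoid, hyoid, soft palate,
#' larynx), with per-direction amplitudes set near the cohort mean motion of
#' each structure, shapes loosely mimicking sagittal anatomy (including the
#' narrow elongate pharyngeal-constrictor band), and 22 frames, a typical
#' contoured swallowing cycle.
#'
#' @param seed base seed; ROI r uses \code{seed + r - 1}.
#' @param nFrames frames per sequence (default 22).
#' @param noiseSd per-point jitter sd in mm (default 0.2).
#' @return Named list of 7 [SyntheticSpec-class] objects.
#' @export
defaultSwallowScene <- function(seed = 1L, nFrames = 22L, noiseSd = 0.2) {
  amp <- function(s, i, a, p)
    c(superior = s, inferior = i, anterior = a, posterior = p)
  rois <- list(
    pharyngeal_constrictor = list(shape = "band",
      params = list(length = 36, width = 4, bow = 2),
      amp = amp(11.1, 9.6, 2.2, 2.0)),
    epiglottis = list(shape = "blob",
      params = list(radius = 6, harmonics = c(0.15, 0.08)),
      amp = amp(12.9, 16.4, 8.8, 4.6)),
    base_of_tongue = list(shape = "blob",
      params = list(radius = 13, harmonics = c(0.1, 0.06)),
      amp = amp(9.8, 9.8, 4.2, 6.0)),
    geniohyoid = list(shape = "ellipse", params = list(a = 12, b = 4),
      amp = amp(6.7, 6.3, 5.3, 1.8)),
    hyoid = list(shape = "ellipse", params = list(a = 6, b = 3),
      amp = amp(13.6, 13.6, 10.6, 3.0)),
    soft_palate = list(shape = "crescent",
      params = list(radius = 14, width = 6, span = 2.6),
      amp = amp(8.3, 7.3, 3.6, 4.9)),
    larynx = list(shape = "ellipse", params = list(a = 14, b = 11),
      amp = amp(18.4, 17.3, 7.0, 4.2)))
  specs <- Map(function(nm, r, k)
    syntheticSpec(nm, shape = r$shape, shapeParams = r$params,
                  amplitudes = r$amp, nFrames = nFrames, warpSd = 0.8,
                  noiseSd = noiseSd, seed = seed + k - 1L),
    names(rois), rois, seq_along(rois))
  specs
}

#' Build one randomized synthetic registration case
#'
#' Draws a single source/target contour pair for benchmarking the matcher:
#' a random shape from the requested family is displaced by a random smooth
#' deformation (translation of random direction with magnitude up to
#' \code{maxAmplitude}, plus a low-order TPS perturbation) and both frames
#' receive per-point Gaussian jitter. The \code{"smooth"} family draws
#' ellipses and blobs; the \code{"elongate"} family draws crescents and
#' moderately elongated bands (5:1 aspect), the shapes the matcher finds
#' hardest short of degeneracy.
#'
#' @param seed integer seed; every random choice derives from it.
#' @param family \code{"smooth"} or \code{"elongate"}.
#' @param maxAmplitude maximum translation magnitude in mm (default 15).
#' @param noiseSd per-point jitter sd in mm (default 0.2).
#' @return A 2-frame [SyntheticSpec-class].
#' @seealso [evaluateRegistrationCase()]
#' @export
syntheticRegistrationCase <- function(seed, family = c("smooth", "elongate"),
                                      maxAmplitude = 15, noiseSd = 0.2) {
  family <- match.arg(family)
  .withSeed(seed, {
    if (family == "smooth") {
      shape <- sample(c("ellipse", "blob"), 1L)
      params <- if (shape == "ellipse")
        list(a = runif(1, 10, 18), b = runif(1, 7, 13))
      else
        list(radius = runif(1, 9, 15),
             harmonics = runif(3, 0.03, 0.12), phases = runif(3, 0, 2 * pi))
      warpSd <- runif(1, 0.5, 2)
    } else {
      shape <- sample(c("crescent", "band"), 1L)
      params <- if (shape == "crescent")
        list(radius = runif(1, 14, 20), width = runif(1, 5, 7),
             span = runif(1, 2.8, 3.6))
      else
        list(length = runif(1, 35, 45), width = runif(1, 7, 9),
             bow = runif(1, 0, 3))
      warpSd <- runif(1, 0.5, 1.5)
    }
    mag <- runif(1, 0, maxAmplitude)
    ang <- runif(1, 0, 2 * pi)
    dx <- mag * cos(ang)
    dy <- mag * sin(ang)
    amp <- c(superior = max(dy, 0), inferior = max(-dy, 0),
             anterior = max(dx, 0), posterior = max(-dx, 0))
    syntheticSpec(paste0(family, "_case_", seed), shape = shape,
                  shapeParams = params, amplitudes = amp, peakFrame = 2L,
                  nFrames = 2L, warpSd = warpSd, noiseSd = noiseSd,
                  seed = seed)
  })
}

#' Generate and register one synthetic case
#'
#' Convenience wrapper used by the benchmark suites: generates the 2-frame
#' sequence of [syntheticRegistrationCase()] (or any 2-frame spec) and
#' registers frame 1 onto frame 2 with [registerPair()].
#'
#' @param spec a [SyntheticSpec-class] with \code{nFrames = 2}, or an
#'   integer seed handed to [syntheticRegistrationCase()].
#' @param family,maxAmplitude,noiseSd passed to
#'   [syntheticRegistrationCase()] when \code{spec} is a seed.
#' @param schedule an [AnnealingSchedule-class].
#' @param spacing resampling/grid spacing in mm.
#' @return The [PairRegistration-class] result.
#' @export
evaluateRegistrationCase <- function(spec, family = "smooth",
                                     maxAmplitude = 15, noiseSd = 0.2,
                                     schedule = annealingSchedule(),
                                     spacing = 1) {
  if (is.numeric(spec))
    spec <- syntheticRegistrationCase(spec, family = family,
                                      maxAmplitude = maxAmplitude,
                                      noiseSd = noiseSd)
  stopifnot(is(spec, "SyntheticSpec"), spec@nFrames == 2L)
  gen <- generateSequence(spec)
  fr <- frames(gen$sequence)
  registerPair(fr[[1L]], fr[[2L]], spacing = spacing, schedule = schedule,
               roi = spec@roi, framePair = c(1L, 2L))
}

#' Run the full pipeline on synthetic data and score it
#'
#' End-to-end recovery harness: generates a sequence from \code{spec},
#' registers all consecutive frame pairs, estimates the motion time course,
#' and reports the per-direction absolute error between the estimated and
#' ground-truth motion summaries together with the registration errors.
#'
#' @param spec a [SyntheticSpec-class].
#' @param schedule an [AnnealingSchedule-class].
#' @param spacing,margin grid parameters (mm).
#' @return A list: \code{summaryError} (named per-direction |estimate -
#'   truth| in mm), \code{meanErrorMm} (mean pairwise registration error),
#'   \code{registrations} (list of [PairRegistration-class]),
#'   \code{estimated} and \code{truth} ([MotionTable-class]s).
#' @export
endToEndRecovery <- function(spec, schedule = annealingSchedule(),
                             spacing = 1, margin = 2) {
  gen <- generateSequence(spec, gridSpacing = spacing, margin = margin)
  regs <- registerSequence(gen$sequence, spacing = spacing,
                           schedule = schedule)
  est <- motionTimecourse(gen$sequence, regs, gridSpacing = spacing,
                          margin = margin)
  list(summaryError = abs(motionSummary(est) - motionSummary(gen$truth)),
       meanErrorMm = mean(vapply(regs, function(r) r@errorMm, numeric(1))),
       registrations = regs, estimated = est, truth = gen$truth)
}

#' The narrow-elongate "reflex" failure scenario
#'
#' Reproduces the known failure mode of contour matching on narrow elongate
#' (pharyngeal-constrictor-like) shapes: a reflex solution in which one long
#' side of the contour is registered onto the opposite side. The scenario is
#' a consecutive-frame pair of a bowed high-aspect band (near-static, so the
#' correct transform is close to the identity) together with the reflex
#' solution made explicit: the thin-plate spline fitted to the side-swapped
#' correspondence that maps every point across the band's long axis. For a
#' bowed band the side-swapped contour mirrors the bow, so it lands several
#' millimetres off the reference and the automatic validation flags the
#' registration — the signature by which such failures are detected in batch
#' runs. (With the default deterministic-annealing schedule the matcher
#' itself resolves this pair correctly; the reflex solution is the local
#' optimum a matcher without sufficient annealing can fall into.)
#'
#' @param seed integer seed for the per-point jitter.
#' @param aspect band aspect ratio (default 10).
#' @param bow bow (curvature) of the band in mm; the reflex error scales
#'   with it.
#' @param noiseSd per-point jitter sd in mm.
#' @return List with elements \code{source} and \code{target}
#'   ([PointSet-class] contours of the pair), \code{reflexTransform} (the
#'   side-swapping [TpsTransform-class]) and \code{reflexed} (the source
#'   contour deformed by the reflex solution).
#' @export
reflexCase <- function(seed = 1L, aspect = 10, bow = 6, noiseSd = 0.1) {
  .withSeed(seed, {
    len <- 40
    wid <- len / aspect
    base <- .shapeBand(length = len, width = wid, bow = bow)
    jit <- function(m) m + matrix(rnorm(length(m), sd = noiseSd), ncol = 2L)
    src <- resampleContour(pointSet(jit(base)), 1)
    tgt <- pointSet(jit(base))
    # the reflex solution: correspondence swapped across the long axis
    V <- coords(src)
    ctrl <- V[seq(1L, nrow(V), by = 3L), , drop = FALSE]
    reflexTf <- tpsSolve(ctrl, cbind(-ctrl[, 1L], ctrl[, 2L]), lam = 0)
    list(source = src, target = tgt, reflexTransform = reflexTf,
         reflexed = transformPoints(reflexTf, src))
  })
}
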