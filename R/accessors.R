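#' @rdname accessors
#' @export
setMethod("coords", "PointSet", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("isClosed", "PointSet", function(x) x@closed)

#' @rdname accessors
#' @export
setMethod("nPoints", "PointSet", function(x) nrow(x@points))

#' @rdname accessors
#' @export
setMethod("roiName", "ContourSequence", function(x) x@roi)

#' @rdname accessors
#' @export
setMethod("frames", "ContourSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("nFrames", "ContourSequence", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "ContourSequence", function(x) x@pixelSpacing)

#' @rdname accessors
#' @export
setMethod("frameIndices", "ContourSequence", function(x) x@frameIndices)

#' @rdname accessors
#' @export
setMethod("frameInterval", "ContourSequence", function(x) x@frameInterval)

#' @rdname accessors
#' @export
setMethod("roiName", "MotionTable", function(x) x@roi)

#' @rdname accessors
#' @export
setMethod("motionSummary", "MotionTable", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("perFrameMotion", "MotionTable", function(x) x@perFrame)

#' @rdname accessors
#' @export
setMethod("roiName", "PairRegistration", function(x) x@roi)

## ------------------------------------------------------------------- show

setMethod("show", "PointSet", function(object) {
  cat(sprintf("PointSet: %d points, %s\n", nrow(object@points),
              if (object@closed) "closed" else "open"))
  bb <- apply(object@points, 2L, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1L, 1L], bb[2L, 1L], bb[1L, 2L], bb[2L, 2L]))
})

setMethod("show", "ContourSequence", function(object) {
  np <- vapply(object@frames, function(f) nrow(f@points), integer(1))
  cat(sprintf("ContourSequence '%s': %d frames (%d-%d points/frame)\n",
              object@roi, length(object@frames), min(np), max(np)))
  cat(sprintf("  pixel spacing %g x %g mm, frame interval %g ms, frames %d..%d\n",
              object@pixelSpacing[1L], object@pixelSpacing[2L],
              object@frameInterval, min(object@frameIndices),
              max(object@frameIndices)))
})

setMethod("show", "TpsTransform", function(object) {
  cat(sprintf("TpsTransform: %d control points\n", nrow(object@controlPoints)))
  cat("  linear:\n")
  print(signif(object@linear, 4))
  cat(sprintf("  translation: (%.4g, %.4g)\n",
              object@translation[1L], object@translation[2L]))
  cat(sprintf("  max |warp coeff|: %.4g, bending energy: %.4g\n",
              if (nrow(object@warpCoeffs)) max(abs(object@warpCoeffs)) else 0,
              bendingEnergy(object)))
})

setMethod("show", "AnnealingSchedule", function(object) {
  cat("AnnealingSchedule:\n")
  cat(sprintf("  tInitFactor %g, tFinalFactor %g, rate %g, innerIters %d\n",
              object@tInitFactor, object@tFinalFactor, object@rate,
              object@innerIters))
  cat(sprintf("  lambdaInit %g, lambda2Init %g, outlierT policy '%s', sinkhorn tol %g / %d sweeps\n",
              object@lambdaInit, object@lambda2Init, object@outlierTPolicy,
              object@sinkhornTol, object@sinkhornMaxSweeps))
})

setMethod("show", "GridDefinition", function(object) {
  cat(sprintf("GridDefinition: %d x %d points, spacing %g mm, origin (%g, %g)\n",
              object@dims[1L], object@dims[2L], object@spacing,
              object@origin[1L], object@origin[2L]))
})

setMethod("show", "DeformationField", function(object) {
  show(object@grid)
  mag <- sqrt(object@dx^2 + object@dy^2)
  cat(sprintf("DeformationField: %d/%d grid points inside ROI, |d| max %.3g mm\n",
              sum(object@inside), length(object@inside), max(mag)))
})

setMethod("show", "MotionTable", function(object) {
  cat(sprintf("MotionTable '%s': %d frames\n", object@roi,
              nrow(object@perFrame)))
  cat("  max over frames (mm):\n")
  print(signif(object@summary, 4))
})

setMethod("show", "PairRegistration", function(object) {
  cat(sprintf("PairRegistration%s frames %s -> %s: error %.3g mm [%s]\n",
              if (nzchar(object@roi)) paste0(" '", object@roi, "'") else "",
              object@framePair[1L], object@framePair[2L], object@errorMm,
              object@status))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec '%s': %s, %d frames, peak at %d, seed %d\n",
              object@roi, object@shape, object@nFrames, object@peakFrame,
              object@seed))
  cat(sprintf("  amplitudes S/I/A/P = %s mm, warpSd %g, noiseSd %g, outliers %g\n",
              paste(signif(object@amplitudes, 3), collapse = "/"),
              object@warpSd, object@noiseSd, object@outlierFraction))
})

#' @describeIn DeformationField-class flatten to a data.frame with columns
#'   \code{row}, \code{col}, \code{x_mm}, \code{y_mm}, \code{dx_mm},
#'   \code{dy_mm}, \code{inside} (\code{col} indexes x, \code{row} indexes y).
#' @param x a DeformationField.
#' @param row.names,optional,... passed on conventionally (ignored).
#' @export
setMethod("as.data.frame", "DeformationField",
          function(x, row.names = NULL, optional = FALSE, ...) {
  g <- x@grid
  ix <- rep(seq_len(g@dims[1L]), times = g@dims[2L])
  iy <- rep(seq_len(g@dims[2L]), each = g@dims[1L])
  data.frame(row = iy, col = ix,
             x_mm = g@origin[1L] + (ix - 1L) * g@spacing,
             y_mm = g@origin[2L] + (iy - 1L) * g@spacing,
             dx_mm = as.vector(x@dx), dy_mm = as.vector(x@dy),
             inside = as.vector(x@inside))
})
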