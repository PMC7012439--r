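#' Decompose displacement vectors into anatomical directions
#'
#' Orthogonally decomposes displacement vectors into the
#' superior-inferior and anterior-posterior axes and rectifies each
#' component: with \eqn{s = v \cdot \hat{si}}, the superior magnitude is
#' \eqn{\max(s, 0)} and the inferior magnitude \eqn{\max(-s, 0)}, and
#' analogously for anterior/posterior. At most one of each opposed pair is
#' nonzero, and superior + inferior equals \eqn{|v \cdot \hat{si}|} exactly.
#'
#' @param v a displacement vector (length 2, mm) or an n x 2 matrix of
#'   vectors.
#' @param frame an [AnatomicalFrame-class].
#' @return For a single vector, a named numeric of length 4; for a matrix,
#'   an n x 4 matrix with columns superior, inferior, anterior, posterior.
#' @examples
#' decomposeVector(c(3, -4), anatomicalFrame())
#' @export
decomposeVector <- function(v, frame = anatomicalFrame()) {
  stopifnot(is(frame, "AnatomicalFrame"))
  single <- is.null(dim(v))
  m <- .asCoordMatrix(v)
  if (!all(is.finite(m))) stop("displacement vectors must be finite")
  s <- as.numeric(m %*% frame@si)
  a <- as.numeric(m %*% frame@ap)
  out <- cbind(superior = pmax(s, 0), inferior = pmax(-s, 0),
               anterior = pmax(a, 0), posterior = pmax(-a, 0))
  if (single) out[1L, ] else out
}

#' Mean directional motion of a deformation field inside the ROI
#'
#' The motion magnitude of one ROI in each direction is the average of that
#' direction's rectified displacement component over all grid points inside
#' the ROI. Each grid point therefore contributes only to the direction it
#' actually moves in.
#'
#' @param field a [DeformationField-class] with at least one inside grid
#'   point.
#' @param frame an [AnatomicalFrame-class].
#' @return Named numeric length 4 (superior, inferior, anterior, posterior),
#'   in mm.
#' @export
roiMotion <- function(field, frame = anatomicalFrame()) {
  stopifnot(is(field, "DeformationField"))
  keep <- as.vector(field@inside)
  if (!any(keep))
    stop("no grid points inside the ROI contour; cannot average motion")
  v <- cbind(as.vector(field@dx)[keep], as.vector(field@dy)[keep])
  mags <- colMeans(decomposeVector(v, frame))
  setNames(as.numeric(mags), .DIRECTIONS)
}

#' Per-frame directional motion of one ROI over a cine sequence
#'
#' Builds the ROI's motion time course: for each contoured frame k the
#' consecutive-frame transforms 1->2, ..., (k-1)->k are composed
#' ([concatenateTransforms()]) and evaluated on a uniform grid over the
#' initial-frame contour, so every frame's motion is the displacement
#' relative to the first contoured frame (pre-swallow rest), not to its
#' neighbour. Magnitudes are averaged over grid points inside the
#' initial-frame ROI ([roiMotion()]); the summary is the per-direction
#' maximum over frames, the quantity used to characterise a structure's
#' motion over the swallowing cycle.
#'
#' @param seq a [ContourSequence-class].
#' @param transforms list of length \code{nFrames(seq) - 1} of mm-space
#'   [TpsTransform-class] objects for consecutive pairs, or the list of
#'   [PairRegistration-class] results from [registerSequence()].
#' @param frame an [AnatomicalFrame-class].
#' @param gridSpacing grid spacing in mm (default 1, the pixel size).
#' @param margin grid margin in mm (default 2).
#' @return A [MotionTable-class]; its \code{perFrame} rows use the
#'   sequence's original frame indices.
#' @export
motionTimecourse <- function(seq, transforms, frame = anatomicalFrame(),
                             gridSpacing = 1, margin = 2) {
  stopifnot(is(seq, "ContourSequence"))
  if (length(transforms) &&
      all(vapply(transforms, is, logical(1), "PairRegistration")))
    transforms <- lapply(transforms, function(r) r@transform)
  if (length(transforms) != nFrames(seq) - 1L)
    stop("need one transform per consecutive frame pair (nFrames - 1)")

  first <- frames(seq)[[1L]]
  grid <- makeGrid(first, spacing = gridSpacing, margin = margin)
  g <- gridPoints(grid)
  inside <- .insidePolygon(g, first@points)
  if (!any(inside))
    stop(sprintf("ROI '%s': no grid points inside the initial contour",
                 roiName(seq)))

  n <- nFrames(seq)
  mags <- matrix(0, n, 4L, dimnames = list(NULL, .DIRECTIONS))
  p <- g
  for (k in seq_len(n - 1L)) {
    p <- transformPoints(transforms[[k]], p)
    d <- (p - g)[inside, , drop = FALSE]
    mags[k + 1L, ] <- colMeans(decomposeVector(d, frame))
  }
  pf <- data.frame(frame = frameIndices(seq), mags)
  motionTable(roiName(seq), pf)
}

#' Plot per-frame directional motion
#'
#' Direction-versus-frame curves of one or several ROIs' motion tables, the
#' standard way to locate the peak swallow and judge which structures move.
#'
#' @param tables a [MotionTable-class] or a list of them.
#' @param direction one of \code{"superior"}, \code{"inferior"},
#'   \code{"anterior"}, \code{"posterior"}.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix of magnitudes.
#' @importFrom graphics matplot legend
#' @importFrom grDevices hcl.colors
#' @export
plotMotion <- function(tables, direction = "inferior", ...) {
  direction <- match.arg(direction, .DIRECTIONS)
  if (is(tables, "MotionTable")) tables <- list(tables)
  fr <- perFrameMotion(tables[[1L]])$frame
  y <- vapply(tables, function(t) perFrameMotion(t)[[direction]],
              numeric(length(fr)))
  cols <- hcl.colors(max(2L, length(tables)), "Dark 2")[seq_along(tables)]
  matplot(fr, y, type = "l", lty = 1L, lwd = 2L, col = cols,
          xlab = "frame", ylab = sprintf("%s motion (mm)", direction), ...)
  legend("topleft", legend = vapply(tables, roiName, character(1)),
         col = cols, lty = 1L, lwd = 2L, bty = "n", cex = 0.8)
  invisible(y)
}
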