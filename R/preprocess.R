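#' Resample a contour to uniform arc-length spacing
#'
#' Re-distributes the points of a contour uniformly along its perimeter so
#' that consecutive points are separated by (close to) a fixed arc length,
#' tied by default to the in-plane image resolution. Point sets from
#' different frames thereby acquire comparable densities before matching.
#'
#' Closed contours are first normalised deterministically: orientation is
#' made counter-clockwise and traversal starts at the vertex with the lowest
#' y (ties broken by lowest x), so repeated runs are bit-identical. The
#' actual separation is \code{L / round(L / spacing)} for perimeter
#' \code{L}, i.e. the closest uniform division of the contour to the
#' requested spacing.
#'
#' @param ps a [PointSet-class].
#' @param spacing target arc-length separation in mm; default 1 mm, the
#'   in-plane pixel size of the cine protocol.
#' @return A resampled [PointSet-class]; all returned points lie on the
#'   original polyline/polygon.
#' @examples
#' circ <- pointSet(15 * cbind(cos(seq(0, 2 * pi, length.out = 200)[-200]),
#'                             sin(seq(0, 2 * pi, length.out = 200)[-200])))
#' nPoints(resampleContour(circ, spacing = 1))  # ~ perimeter in mm
#' @export
resampleContour <- function(ps, spacing = 1) {
  stopifnot(is(ps, "PointSet"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar (mm)")
  pts <- ps@points
  closed <- ps@closed

  if (closed) {
    if (.signedArea(pts) < 0)  # normalise to counter-clockwise
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    start <- order(pts[, 2L], pts[, 1L])[1L]
    if (start > 1L)
      pts <- pts[c(start:nrow(pts), 1:(start - 1L)), , drop = FALSE]
    verts <- rbind(pts, pts[1L, ])
  } else {
    verts <- pts
  }

  s <- .arcLengths(verts)
  L <- s[length(s)]
  if (L < 2 * spacing)
    stop(sprintf(
      "degenerate contour: total length %.3g mm is below twice the spacing (%g mm)",
      L, spacing))

  if (closed) {
    n <- max(3L, as.integer(round(L / spacing)))
    targets <- (seq_len(n) - 1L) * (L / n)
  } else {
    nSeg <- max(2L, as.integer(round(L / spacing)))
    targets <- (0:nSeg) * (L / nSeg)
  }
  out <- cbind(approx(s, verts[, 1L], xout = targets, ties = "ordered")$y,
               approx(s, verts[, 2L], xout = targets, ties = "ordered")$y)
  pointSet(out, closed = closed)
}

#' Compute a unit-box scaling for one or more point sets
#'
#' Returns the isotropic similarity mapping the union bounding box of the
#' inputs into the unit box \eqn{[0,1]^2}: \code{u = (x - offset) / scale}
#' with \code{scale} the larger side of the union box. Using one shared
#' scaling for the source and target of a registration keeps the two sets in
#' a common frame and preserves shape (all pairwise distance ratios).
#'
#' @param x a [PointSet-class], a coordinate matrix, or a list of either.
#' @return A [UnitBoxScaling-class].
#' @examples
#' a <- pointSet(rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
#' unitBoxScaling(a)
#' @export
unitBoxScaling <- function(x) {
  if (!is.list(x) || is(x, "PointSet")) x <- list(x)
  pts <- do.call(rbind, lapply(x, .asCoordMatrix))
  lo <- c(min(pts[, 1L]), min(pts[, 2L]))
  hi <- c(max(pts[, 1L]), max(pts[, 2L]))
  scale <- max(hi - lo)
  if (scale <= 0)
    stop("degenerate bounding box: all points coincide")
  new("UnitBoxScaling", offset = lo, scale = scale)
}

#' Map a point set into the unit box
#'
#' @param ps a [PointSet-class].
#' @param scaling a [UnitBoxScaling-class]; computed from \code{ps} itself
#'   when omitted. For pairwise registration pass the shared scaling of both
#'   sets (see [unitBoxScaling()]).
#' @return A list with elements \code{points} (the rescaled
#'   [PointSet-class]) and \code{scaling}.
#' @seealso [fromUnitBox()]
#' @examples
#' a <- pointSet(rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
#' u <- toUnitBox(a)
#' range(coords(u$points))
#' @export
toUnitBox <- function(ps, scaling = NULL) {
  stopifnot(is(ps, "PointSet"))
  if (is.null(scaling)) scaling <- unitBoxScaling(ps)
  stopifnot(is(scaling, "UnitBoxScaling"))
  u <- sweep(ps@points, 2L, scaling@offset, "-") / scaling@scale
  list(points = pointSet(u, closed = ps@closed), scaling = scaling)
}

#' Map a point set back from the unit box to mm coordinates
#'
#' Exact inverse of [toUnitBox()] for the same scaling.
#'
#' @param ps a [PointSet-class] in unit-box coordinates.
#' @param scaling the [UnitBoxScaling-class] used by [toUnitBox()].
#' @return A [PointSet-class] in mm.
#' @export
fromUnitBox <- function(ps, scaling) {
  stopifnot(is(ps, "PointSet"), is(scaling, "UnitBoxScaling"))
  x <- sweep(ps@points * scaling@scale, 2L, scaling@offset, "+")
  pointSet(x, closed = ps@closed)
}
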