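#' Build a uniform grid over a contour
#'
#' Axis-aligned uniform grid covering the contour's bounding box expanded by
#' \code{margin}, with the origin snapped down to a multiple of the spacing
#' so grid placement is deterministic and independent of sub-millimetre
#' bounding-box jitter.
#'
#' @param contour a [PointSet-class] (or coordinate matrix).
#' @param spacing grid spacing in mm; default 1 mm, the in-plane pixel size.
#' @param margin extra margin around the bounding box in mm; default 2.
#' @return A [GridDefinition-class].
#' @examples
#' sq <- pointSet(rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
#' makeGrid(sq, spacing = 1, margin = 1)  # 13 x 8 points
#' @export
makeGrid <- function(contour, spacing = 1, margin = 2) {
  if (spacing <= 0) stop("spacing must be positive")
  if (margin < 0) stop("margin must be >= 0")
  pts <- .asCoordMatrix(contour)
  lo <- c(min(pts[, 1L]), min(pts[, 2L])) - margin
  hi <- c(max(pts[, 1L]), max(pts[, 2L])) + margin
  origin <- floor(lo / spacing) * spacing
  dims <- as.integer(floor((hi - origin) / spacing + 1e-9)) + 1L
  new("GridDefinition", origin = origin, spacing = spacing, dims = dims)
}

#' Coordinates of all grid points
#'
#' @param grid a [GridDefinition-class].
#' @return An (nx * ny) x 2 matrix; the x index varies fastest, matching the
#'   \code{[ix, iy]} layout of [DeformationField-class] matrices.
#' @export
gridPoints <- function(grid) {
  stopifnot(is(grid, "GridDefinition"))
  xs <- grid@origin[1L] + (seq_len(grid@dims[1L]) - 1L) * grid@spacing
  ys <- grid@origin[2L] + (seq_len(grid@dims[2L]) - 1L) * grid@spacing
  cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
}

.fieldFromVectors <- function(grid, vec, contour) {
  inside <- .insidePolygon(gridPoints(grid), .asCoordMatrix(contour))
  d <- grid@dims
  new("DeformationField", grid = grid,
      dx = matrix(vec[, 1L], d[1L], d[2L]),
      dy = matrix(vec[, 2L], d[1L], d[2L]),
      inside = matrix(inside, d[1L], d[2L]))
}

#' Sample a transform as a deformation vector field
#'
#' Evaluates an mm-space transform at every grid point \eqn{g} and stores the
#' displacement \eqn{f(g) - g}, together with a mask of grid points inside
#' the ROI contour (even-odd rule; boundary points count as inside, so the
#' contour itself contributes to motion).
#'
#' @param transform a [TpsTransform-class] in mm coordinates.
#' @param grid a [GridDefinition-class] in the same frame.
#' @param contour the ROI [PointSet-class] defining the inside mask
#'   (normally the contour at the field's start frame).
#' @return A [DeformationField-class].
#' @export
evaluateField <- function(transform, grid, contour) {
  stopifnot(is(transform, "TpsTransform"), is(grid, "GridDefinition"))
  g <- gridPoints(grid)
  .fieldFromVectors(grid, transformPoints(transform, g) - g, contour)
}

#' Compose consecutive-frame transforms into one deformation field
#'
#' For motion between non-adjacent frames the consecutive-frame transforms
#' connecting them are concatenated: each grid point is pushed through every
#' transform in order (\eqn{p \leftarrow f_k(p)}) and the field stores
#' \eqn{p - g}. Because TPS transforms are analytic and globally defined, the
#' composition re-evaluates each transform at the moved position rather than
#' interpolating gridded vectors, so no resampling error accumulates. An
#' empty transform list yields the zero field.
#'
#' @param transforms ordered list of [TpsTransform-class] objects for frame
#'   pairs \eqn{i \to i+1, \ldots, j-1 \to j} (mm coordinates).
#' @param grid a [GridDefinition-class].
#' @param contour ROI contour at the start frame \eqn{i}, used for the
#'   inside mask.
#' @return A [DeformationField-class] for the motion \eqn{i \to j}.
#' @export
concatenateTransforms <- function(transforms, grid, contour) {
  stopifnot(is(grid, "GridDefinition"))
  g <- gridPoints(grid)
  p <- g
  for (f in transforms) {
    stopifnot(is(f, "TpsTransform"))
    p <- transformPoints(f, p)
  }
  .fieldFromVectors(grid, p - g, contour)
}

#' Write a deformation field to CSV
#'
#' Flat-file export of a [DeformationField-class]: one row per grid point
#' with columns \code{row}, \code{col}, \code{x_mm}, \code{y_mm},
#' \code{dx_mm}, \code{dy_mm}, \code{inside}.
#'
#' @param field a [DeformationField-class].
#' @param path output file path.
#' @return Invisibly, the written data.frame.
#' @export
writeDeformationField <- function(field, path) {
  stopifnot(is(field, "DeformationField"))
  df <- as.data.frame(field)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
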