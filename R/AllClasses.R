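#' @import methods
NULL

.DIRECTIONS <- c("superior", "inferior", "anterior", "posterior")

## ---------------------------------------------------------------- PointSet

#' PointSet: an ordered 2D contour or polyline
#'
#' The basic unit of registration: an ordered set of 2D points in physical
#' coordinates (millimetres), with a flag saying whether the point list wraps
#' around (a closed contour) or is an open polyline.
#'
#' @slot points numeric matrix with one row per point and two columns (x, y),
#'   in mm. By convention +x points anterior and +y points superior on a
#'   sagittal frame.
#' @slot closed logical flag; \code{TRUE} for closed contours.
#'
#' @seealso [pointSet()], [resampleContour()], [toUnitBox()]
#' @exportClass PointSet
setClass("PointSet",
         representation(points = "matrix", closed = "logical"))

setValidity("PointSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L)
    return("points must be a numeric matrix with two columns (x, y)")
  if (nrow(p) < 3L)
    return("a PointSet needs at least 3 points")
  if (!all(is.finite(p)))
    return("points must be finite")
  if (length(object@closed) != 1L || is.na(object@closed))
    return("closed must be a single TRUE/FALSE")
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(d == 0))
    return("consecutive points must be distinct")
  TRUE
})

#' Create a PointSet
#'
#' @param points two-column numeric matrix (or object coercible to one) of
#'   (x, y) coordinates in mm.
#' @param closed logical; is the contour closed? Default \code{TRUE}.
#' @return A [PointSet-class] object.
#' @examples
#' sq <- pointSet(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' sq
#' @export
pointSet <- function(points, closed = TRUE) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  new("PointSet", points = pts, closed = closed)
}

## ---------------------------------------------------------- ContourSequence

#' ContourSequence: one ROI contoured over consecutive cine frames
#'
#' Holds the ordered per-frame contours of a single region of interest (ROI)
#' delineated on consecutive frames of a 2D MR cine scan, together with the
#' acquisition metadata needed to interpret them (pixel spacing and frame
#' interval).
#'
#' @slot roi character ROI label (e.g. \code{"larynx"}).
#' @slot frames list of [PointSet-class] contours, one per contoured frame,
#'   all in the same mm coordinate frame.
#' @slot pixelSpacing numeric length-2, mm per pixel as (row, column).
#' @slot frameInterval numeric, time between frames in ms.
#' @slot frameIndices integer, original cine frame numbers (strictly
#'   increasing).
#'
#' @seealso [contourSequence()], [readContourSequence()], [motionTimecourse()]
#' @exportClass ContourSequence
setClass("ContourSequence",
         representation(roi = "character", frames = "list",
                        pixelSpacing = "numeric", frameInterval = "numeric",
                        frameIndices = "integer"))

setValidity("ContourSequence", function(object) {
  if (length(object@roi) != 1L || is.na(object@roi) || !nzchar(object@roi))
    return("roi must be a non-empty label")
  if (length(object@frames) < 2L)
    return("a ContourSequence needs at least 2 frames")
  ok <- vapply(object@frames, function(f)
    is(f, "PointSet") && nrow(f@points) >= 3L, logical(1))
  if (!all(ok))
    return(sprintf("frame %d is not a valid PointSet with >= 3 points",
                   which(!ok)[1L]))
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be two positive values (mm)")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a positive scalar (ms)")
  fi <- object@frameIndices
  if (length(fi) != length(object@frames))
    return("frameIndices must match the number of frames")
  if (any(diff(fi) <= 0L))
    return("frameIndices must be strictly increasing")
  TRUE
})

#' Create a ContourSequence
#'
#' @param roi ROI label.
#' @param frames list of [PointSet-class] contours (all sharing one
#'   coordinate frame).
#' @param pixelSpacing mm per pixel, (row, column). Default \code{c(1, 1)},
#'   the in-plane resolution of a typical swallowing cine protocol.
#' @param frameInterval frame interval in ms. Default 160.
#' @param frameIndices original cine frame numbers; defaults to
#'   \code{seq_along(frames)}.
#' @return A [ContourSequence-class] object.
#' @export
contourSequence <- function(roi, frames, pixelSpacing = c(1, 1),
                            frameInterval = 160,
                            frameIndices = seq_along(frames)) {
  new("ContourSequence", roi = as.character(roi), frames = frames,
      pixelSpacing = as.numeric(pixelSpacing),
      frameInterval = as.numeric(frameInterval),
      frameIndices = as.integer(frameIndices))
}

## ------------------------------------------------------------ UnitBoxScaling

#' UnitBoxScaling: similarity map between mm coordinates and the unit box
#'
#' Isotropic scaling used to map point sets into \eqn{[0,1]^2} before
#' matching and back afterwards: \code{u = (x - offset) / scale}.
#'
#' @slot offset numeric length-2 translation (mm).
#' @slot scale positive scalar (mm per unit-box unit).
#' @seealso [unitBoxScaling()], [toUnitBox()], [fromUnitBox()]
#' @exportClass UnitBoxScaling
setClass("UnitBoxScaling",
         representation(offset = "numeric", scale = "numeric"))

setValidity("UnitBoxScaling", function(object) {
  if (length(object@offset) != 2L || !all(is.finite(object@offset)))
    return("offset must be two finite values")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    return("scale must be a positive scalar")
  TRUE
})

## -------------------------------------------------------------- TpsTransform

#' TpsTransform: analytic 2D thin-plate-spline warp
#'
#' A thin-plate-spline (TPS) transform \deqn{f(x) = x L + t + \sum_j w_j
#' U(\|x - v_j\|),} with radial kernel \eqn{U(r) = r^2 \log r}
#' (\eqn{U(0) = 0}), affine part \eqn{(L, t)} and per-control-point warp
#' coefficients \eqn{w_j}. The coefficients satisfy the TPS side conditions
#' \eqn{\sum_j w_j = 0} and \eqn{\sum_j w_j v_j = 0}, so the warp behaves
#' affinely at infinity and has finite bending energy.
#'
#' @slot controlPoints K x 2 matrix of control points \eqn{v_j}.
#' @slot linear 2 x 2 matrix; row-vector convention (\code{y = x \%*\% linear
#'   + translation + warp}).
#' @slot translation numeric length-2.
#' @slot warpCoeffs K x 2 matrix of kernel coefficients \eqn{w_j}.
#' @seealso [tpsSolve()], [transformPoints()], [rescaleTransform()],
#'   [bendingEnergy()]
#' @exportClass TpsTransform
setClass("TpsTransform",
         representation(controlPoints = "matrix", linear = "matrix",
                        translation = "numeric", warpCoeffs = "matrix"))

setValidity("TpsTransform", function(object) {
  V <- object@controlPoints
  W <- object@warpCoeffs
  if (ncol(V) != 2L || ncol(W) != 2L || nrow(V) != nrow(W))
    return("controlPoints and warpCoeffs must be K x 2 matrices")
  if (!all(dim(object@linear) == c(2L, 2L)))
    return("linear must be a 2 x 2 matrix")
  if (length(object@translation) != 2L)
    return("translation must be length 2")
  if (!all(is.finite(V)) || !all(is.finite(W)) ||
      !all(is.finite(object@linear)) || !all(is.finite(object@translation)))
    return("all transform components must be finite")
  if (nrow(W) > 0L) {
    # side conditions, scaled by coefficient magnitude and control-point extent
    ref <- max(1, max(abs(W)) * max(1, max(abs(V))))
    if (max(abs(colSums(W))) > 1e-6 * ref)
      return("warp coefficients violate sum(w) = 0 side condition")
    if (max(abs(crossprod(V, W))) > 1e-6 * ref)
      return("warp coefficients violate first-moment side condition")
  }
  TRUE
})

## ---------------------------------------------------------- AnnealingSchedule

#' AnnealingSchedule: deterministic-annealing parameters for TPS-RPM
#'
#' The schedule controls how correspondence fuzziness (temperature) and
#' transform rigidity (TPS regularisation) are relaxed over the outer
#' annealing loop. Temperatures are expressed through data-driven factors:
#' the initial temperature is \code{tInitFactor} times the mean squared
#' source-target distance in the unit box, and the final temperature is
#' \code{tFinalFactor} times the squared unit-box resampling spacing. The
#' default final factor of 0.04 cools well below the squared point spacing: at
#' temperatures near the squared spacing the Gaussian affinities of
#' neighbouring contour points are still appreciable, which blends virtual
#' targets along the contour and leaves a curvature-dependent bias; cooling
#' on towards a few percent of the squared spacing makes the correspondence
#' effectively binary.
#'
#' @slot tInitFactor multiplier for the initial temperature. Default 1.
#' @slot tFinalFactor multiplier for the final temperature. Default 0.04.
#' @slot rate multiplicative cooling factor per outer iteration, in (0, 1).
#'   Default 0.93.
#' @slot innerIters correspondence/transform alternations per temperature.
#'   Default 3.
#' @slot lambdaInit TPS bending-energy weight; the effective penalty is
#'   \code{lambdaInit * T * K} so early (hot) iterations are near-rigid.
#'   Default 1.
#' @slot lambda2Init affine-identity ridge weight, annealed the same way
#'   (\code{lambda2Init * T * K}); it anchors the affine part to the
#'   identity while correspondence is still fuzzy and vanishes as the
#'   temperature falls. Default 0.01.
#' @slot outlierTPolicy how the outlier-bin temperature is set; only
#'   \code{"t-init"} (hold it at the initial temperature) is implemented.
#' @slot sinkhornTol row/column-sum tolerance for softassign normalisation.
#'   Default 1e-3.
#' @slot sinkhornMaxSweeps maximum alternating normalisation sweeps.
#'   Default 30.
#' @seealso [annealingSchedule()], [annealRegister()], [registerPair()]
#' @exportClass AnnealingSchedule
setClass("AnnealingSchedule",
         representation(tInitFactor = "numeric", tFinalFactor = "numeric",
                        rate = "numeric", innerIters = "integer",
                        lambdaInit = "numeric", lambda2Init = "numeric",
                        outlierTPolicy = "character",
                        sinkhornTol = "numeric", sinkhornMaxSweeps = "integer"))

setValidity("AnnealingSchedule", function(object) {
  if (object@rate <= 0 || object@rate >= 1)
    return("rate must be in (0, 1)")
  if (object@tInitFactor <= 0 || object@tFinalFactor <= 0)
    return("temperature factors must be positive")
  if (object@innerIters < 1L)
    return("innerIters must be >= 1")
  if (object@lambdaInit <= 0)
    return("lambdaInit must be positive")
  if (object@lambda2Init < 0)
    return("lambda2Init must be >= 0")
  if (!identical(object@outlierTPolicy, "t-init"))
    return("only outlierTPolicy = 't-init' is implemented")
  if (object@sinkhornTol <= 0 || object@sinkhornMaxSweeps < 1L)
    return("sinkhornTol must be > 0 and sinkhornMaxSweeps >= 1")
  TRUE
})

#' Create an annealing schedule
#'
#' Returns the deterministic-annealing schedule used by [annealRegister()]
#' and [registerPair()]. The defaults are the package's documented standard
#' schedule; all parameters are exposed so difficult registrations can be
#' re-run with adjusted settings.
#'
#' @param tInitFactor,tFinalFactor,rate,innerIters,lambdaInit,lambda2Init,outlierTPolicy,sinkhornTol,sinkhornMaxSweeps
#'   see [AnnealingSchedule-class].
#' @return An [AnnealingSchedule-class] object.
#' @examples
#' annealingSchedule()
#' annealingSchedule(rate = 0.9, innerIters = 5)
#' @export
annealingSchedule <- function(tInitFactor = 1, tFinalFactor = 0.04, rate = 0.93,
                              innerIters = 3L, lambdaInit = 1,
                              lambda2Init = 0.01,
                              outlierTPolicy = "t-init", sinkhornTol = 1e-3,
                              sinkhornMaxSweeps = 30L) {
  new("AnnealingSchedule", tInitFactor = tInitFactor,
      tFinalFactor = tFinalFactor, rate = rate,
      innerIters = as.integer(innerIters), lambdaInit = lambdaInit,
      lambda2Init = lambda2Init,
      outlierTPolicy = outlierTPolicy, sinkhornTol = sinkhornTol,
      sinkhornMaxSweeps = as.integer(sinkhornMaxSweeps))
}

## ------------------------------------------------------------ GridDefinition

#' GridDefinition: a uniform 2D sampling grid
#'
#' Axis-aligned uniform grid on which deformation vector fields are sampled.
#' Grid point \code{(ix, iy)} sits at \code{origin + (ix - 1, iy - 1) *
#' spacing}.
#'
#' @slot origin numeric length-2, mm (x, y of the first grid point).
#' @slot spacing positive scalar, mm.
#' @slot dims integer length-2: number of grid points along x and y.
#' @seealso [makeGrid()], [gridPoints()]
#' @exportClass GridDefinition
setClass("GridDefinition",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer"))

setValidity("GridDefinition", function(object) {
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    return("origin must be two finite values")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar")
  if (length(object@dims) != 2L || any(object@dims < 1L))
    return("dims must be two positive counts")
  TRUE
})

## ---------------------------------------------------------- DeformationField

#' DeformationField: displacement vectors sampled on a uniform grid
#'
#' Displacements (mm) of each grid point under a transform (or a composition
#' of transforms), together with a mask of grid points lying inside the ROI
#' contour. Matrices are indexed \code{[ix, iy]} matching the grid's
#' \code{dims}.
#'
#' @slot grid a [GridDefinition-class].
#' @slot dx,dy numeric matrices of x/y displacement components (mm).
#' @slot inside logical matrix; \code{TRUE} for grid points inside (or on)
#'   the ROI contour.
#' @seealso [evaluateField()], [concatenateTransforms()], [roiMotion()]
#' @exportClass DeformationField
setClass("DeformationField",
         representation(grid = "GridDefinition", dx = "matrix", dy = "matrix",
                        inside = "matrix"))

setValidity("DeformationField", function(object) {
  d <- object@grid@dims
  for (nm in c("dx", "dy", "inside")) {
    m <- slot(object, nm)
    if (!all(dim(m) == d))
      return(sprintf("%s must be a %d x %d matrix", nm, d[1L], d[2L]))
  }
  if (!all(is.finite(object@dx)) || !all(is.finite(object@dy)))
    return("displacements must be finite")
  if (!is.logical(object@inside))
    return("inside must be a logical matrix")
  TRUE
})

## ------------------------------------------------------------ AnatomicalFrame

#' AnatomicalFrame: in-plane anatomical axes
#'
#' Orthonormal superior and anterior unit vectors defining the
#' superior-inferior (SI) and anterior-posterior (AP) decomposition of
#' displacement vectors on the sagittal plane.
#'
#' @slot si numeric length-2 unit vector pointing superior.
#' @slot ap numeric length-2 unit vector pointing anterior.
#' @seealso [anatomicalFrame()], [decomposeVector()]
#' @exportClass AnatomicalFrame
setClass("AnatomicalFrame", representation(si = "numeric", ap = "numeric"))

setValidity("AnatomicalFrame", function(object) {
  if (length(object@si) != 2L || length(object@ap) != 2L)
    return("si and ap must be length-2 vectors")
  if (abs(sum(object@si^2) - 1) > 1e-9 || abs(sum(object@ap^2) - 1) > 1e-9)
    return("axes must be unit vectors")
  if (abs(sum(object@si * object@ap)) > 1e-9)
    return("axes must be orthogonal")
  TRUE
})

#' Create an anatomical frame
#'
#' Defaults to the package's sagittal convention: contours live in a
#' right-handed mm frame with +y superior and +x anterior.
#'
#' @param si vector pointing superior (normalised internally).
#' @param ap vector pointing anterior (normalised internally).
#' @return An [AnatomicalFrame-class] object.
#' @export
anatomicalFrame <- function(si = c(0, 1), ap = c(1, 0)) {
  si <- as.numeric(si); ap <- as.numeric(ap)
  si <- si / sqrt(sum(si^2))
  ap <- ap / sqrt(sum(ap^2))
  new("AnatomicalFrame", si = si, ap = ap)
}

## ---------------------------------------------------------------- MotionTable

#' MotionTable: per-frame directional motion of one ROI
#'
#' Per-frame superior/inferior/anterior/posterior motion magnitudes of one
#' ROI, measured against the first contoured frame, plus the per-direction
#' maximum over frames used to characterise the ROI's motion over the
#' swallowing cycle.
#'
#' @slot roi ROI label.
#' @slot perFrame data.frame with columns \code{frame}, \code{superior},
#'   \code{inferior}, \code{anterior}, \code{posterior} (mm).
#' @slot summary named numeric length-4: per-direction maximum over frames.
#' @seealso [motionTimecourse()], [writeMotionTable()], [plotMotion()]
#' @exportClass MotionTable
setClass("MotionTable",
         representation(roi = "character", perFrame = "data.frame",
                        summary = "numeric"))

setValidity("MotionTable", function(object) {
  pf <- object@perFrame
  need <- c("frame", .DIRECTIONS)
  if (!all(need %in% names(pf)))
    return(paste("perFrame must have columns", paste(need, collapse = ", ")))
  mags <- as.matrix(pf[.DIRECTIONS])
  if (any(mags < 0))
    return("motion magnitudes must be non-negative")
  if (!identical(names(object@summary), .DIRECTIONS))
    return("summary must be named superior/inferior/anterior/posterior")
  mx <- apply(mags, 2L, max)
  if (max(abs(mx - object@summary)) > 1e-9)
    return("summary must equal the per-direction maximum over frames")
  if (max(mags[1L, ]) > 1e-9)
    return("the first contoured frame must have all-zero magnitudes")
  TRUE
})

#' Create a MotionTable
#'
#' @param roi ROI label.
#' @param perFrame data.frame of per-frame magnitudes (see
#'   [MotionTable-class]).
#' @param summary optional named per-direction maxima; computed from
#'   \code{perFrame} when omitted.
#' @return A [MotionTable-class] object.
#' @export
motionTable <- function(roi, perFrame, summary = NULL) {
  if (is.null(summary)) {
    summary <- apply(as.matrix(perFrame[.DIRECTIONS]), 2L, max)
    names(summary) <- .DIRECTIONS
  }
  new("MotionTable", roi = as.character(roi),
      perFrame = as.data.frame(perFrame), summary = summary)
}

## ----------------------------------------------------------- PairRegistration

#' PairRegistration: result of registering one consecutive frame pair
#'
#' Bundles the mm-space transform recovered by [registerPair()] with its
#' automatic validation: the symmetric mean contour distance between the
#' deformed source contour and the target contour, and the resulting status
#' flag.
#'
#' @slot roi ROI label (may be \code{""}).
#' @slot framePair integer length-2, (from, to) frame indices.
#' @slot transform the recovered [TpsTransform-class] in mm coordinates.
#' @slot errorMm registration error in mm.
#' @slot status one of \code{"ok"}, \code{"suspect"}, \code{"failed"}.
#' @slot diagnostics list with the annealing trace (\code{trace} data.frame),
#'   unit-box scaling and iteration counts.
#' @seealso [registerPair()], [classifyRun()]
#' @exportClass PairRegistration
setClass("PairRegistration",
         representation(roi = "character", framePair = "integer",
                        transform = "TpsTransform", errorMm = "numeric",
                        status = "character", diagnostics = "list"))

setValidity("PairRegistration", function(object) {
  if (!object@status %in% c("ok", "suspect", "failed"))
    return("status must be ok/suspect/failed")
  if (length(object@errorMm) != 1L || object@errorMm < 0)
    return("errorMm must be a non-negative scalar")
  TRUE
})

## -------------------------------------------------------------- SyntheticSpec

#' SyntheticSpec: recipe for a synthetic contour sequence
#'
#' Describes one synthetic ROI: a parametric base shape, a directional motion
#' model (per-direction amplitudes with a peak frame), a smooth low-order
#' non-rigid perturbation, per-point jitter and optional spurious points.
#' Generation is fully reproducible from \code{seed}.
#'
#' @slot roi ROI label.
#' @slot shape one of \code{"ellipse"}, \code{"blob"}, \code{"crescent"},
#'   \code{"band"}.
#' @slot shapeParams named list of shape parameters (mm); see
#'   [generateSequence()].
#' @slot center numeric length-2 shape centre (mm).
#' @slot amplitudes named numeric length-4 (superior, inferior, anterior,
#'   posterior) peak translation amplitudes in mm.
#' @slot peakFrame frame at which the superior/anterior excursion peaks.
#' @slot nFrames number of frames (>= 2).
#' @slot warpSd standard deviation (mm) of the control-point displacements of
#'   the smooth non-rigid perturbation (0 = pure translation).
#' @slot noiseSd per-point Gaussian jitter sd (mm).
#' @slot outlierFraction fraction of spurious points inserted per frame.
#' @slot pixelSpacing,frameInterval acquisition metadata passed to the
#'   generated [ContourSequence-class].
#' @slot seed integer random seed.
#' @seealso [syntheticSpec()], [generateSequence()], [defaultSwallowScene()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
         representation(roi = "character", shape = "character",
                        shapeParams = "list", center = "numeric",
                        amplitudes = "numeric", peakFrame = "integer",
                        nFrames = "integer", warpSd = "numeric",
                        noiseSd = "numeric", outlierFraction = "numeric",
                        pixelSpacing = "numeric", frameInterval = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (!object@shape %in% c("ellipse", "blob", "crescent", "band"))
    return("shape must be ellipse/blob/crescent/band")
  if (object@nFrames < 2L)
    return("nFrames must be >= 2")
  if (!identical(names(object@amplitudes), .DIRECTIONS))
    return("amplitudes must be named superior/inferior/anterior/posterior")
  if (any(object@amplitudes < 0))
    return("amplitudes must be >= 0")
  if (object@peakFrame < 2L || object@peakFrame > object@nFrames)
    return("peakFrame must be in [2, nFrames]")
  if (object@noiseSd < 0 || object@warpSd < 0)
    return("noiseSd and warpSd must be >= 0")
  if (object@outlierFraction < 0 || object@outlierFraction >= 1)
    return("outlierFraction must be in [0, 1)")
  TRUE
})

#' Create a SyntheticSpec
#'
#' @param roi ROI label.
#' @param shape base shape name; see [SyntheticSpec-class].
#' @param shapeParams named list of shape parameters in mm.
#' @param center shape centre (mm).
#' @param amplitudes named per-direction peak amplitudes in mm; missing
#'   directions default to 0.
#' @param peakFrame frame of peak superior/anterior excursion; defaults to
#'   two-thirds of the sequence.
#' @param nFrames number of frames. Default 22, a typical contoured
#'   swallowing cycle.
#' @param warpSd smooth-perturbation control-point sd (mm). Default 0.
#' @param noiseSd per-point jitter sd (mm). Default 0.
#' @param outlierFraction fraction of spurious points per frame. Default 0.
#' @param pixelSpacing,frameInterval acquisition metadata.
#' @param seed integer seed.
#' @return A [SyntheticSpec-class] object.
#' @examples
#' sp <- syntheticSpec("larynx", amplitudes = c(superior = 18, inferior = 17))
#' gen <- generateSequence(sp)
#' gen$truth
#' @export
syntheticSpec <- function(roi = "roi", shape = "ellipse",
                          shapeParams = list(), center = c(0, 0),
                          amplitudes = c(superior = 10),
                          peakFrame = NULL, nFrames = 22L, warpSd = 0,
                          noiseSd = 0, outlierFraction = 0,
                          pixelSpacing = c(1, 1), frameInterval = 160,
                          seed = 1L) {
  amp <- setNames(numeric(4L), .DIRECTIONS)
  if (length(amplitudes)) {
    if (is.null(names(amplitudes)) ||
        !all(names(amplitudes) %in% .DIRECTIONS))
      stop("amplitudes must be named with directions ",
           paste(.DIRECTIONS, collapse = "/"))
    amp[names(amplitudes)] <- amplitudes
  }
  nFrames <- as.integer(nFrames)
  if (is.null(peakFrame))
    peakFrame <- max(2L, as.integer(round(2 * nFrames / 3)))
  new("SyntheticSpec", roi = as.character(roi), shape = shape,
      shapeParams = shapeParams, center = as.numeric(center),
      amplitudes = amp, peakFrame = as.integer(peakFrame), nFrames = nFrames,
      warpSd = warpSd, noiseSd = noiseSd, outlierFraction = outlierFraction,
      pixelSpacing = as.numeric(pixelSpacing),
      frameInterval = as.numeric(frameInterval), seed = as.integer(seed))
}
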