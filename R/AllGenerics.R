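#' Accessor generics
#'
#' Accessors for the package's S4 classes: point coordinates, contour
#' topology, sequence metadata and motion summaries.
#'
#' @param x,object an object of the relevant class.
#' @name accessors
#' @return \code{coords}: a numeric matrix of (x, y) coordinates;
#'   \code{isClosed}: logical; \code{nPoints}, \code{nFrames}: integer;
#'   \code{frames}: list of [PointSet-class]; \code{roiName}: character;
#'   \code{pixelSpacing}, \code{frameIndices}, \code{frameInterval},
#'   \code{motionSummary}: numeric; \code{perFrameMotion}: data.frame;
#'   \code{registrationStatus}, \code{registrationError<-}... see methods.
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("isClosed", function(x) standardGeneric("isClosed"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("roiName", function(x) standardGeneric("roiName"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("frameIndices", function(x) standardGeneric("frameIndices"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("motionSummary", function(x) standardGeneric("motionSummary"))

#' @rdname accessors
#' @export
setGeneric("perFrameMotion", function(x) standardGeneric("perFrameMotion"))

#' Evaluate a transform at query points
#'
#' @param transform a [TpsTransform-class].
#' @param points a [PointSet-class] or a two-column coordinate matrix.
#' @return An object of the same kind as \code{points} with mapped
#'   coordinates.
#' @examples
#' sq <- coords(pointSet(rbind(c(0,0), c(1,0), c(1,1), c(0,1))))
#' tf <- tpsSolve(sq, sq + 2)   # pure translation
#' transformPoints(tf, rbind(c(0.5, 0.5)))
#' @export
setGeneric("transformPoints",
           function(transform, points) standardGeneric("transformPoints"))
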