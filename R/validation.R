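#' Registration error between a deformed and a reference contour
#'
#' Symmetric mean closest-point distance between two contours: the average
#' distance from each point of the deformed contour to the reference
#' polyline plus the average distance from each reference point to the
#' deformed polyline, divided by two. Resampling destroys index
#' correspondence between frames, so distances are taken to the nearest
#' point on the opposing contour (its segments), not to same-index points.
#' The measure is symmetric, invariant under a common rigid motion of both
#' contours, and zero exactly when the contours coincide.
#'
#' @param deformed,reference [PointSet-class] contours in mm.
#' @return Mean distance in mm (non-negative scalar).
#' @examples
#' sq <- pointSet(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' registrationError(sq, sq)
#' @export
registrationError <- function(deformed, reference) {
  stopifnot(is(deformed, "PointSet"), is(reference, "PointSet"))
  a <- mean(.distToPolyline(deformed@points, reference@points,
                            closed = reference@closed))
  b <- mean(.distToPolyline(reference@points, deformed@points,
                            closed = deformed@closed))
  (a + b) / 2
}

#' Classify a batch of registrations by error
#'
#' Applies the automatic validation rule to a set of registration errors:
#' registrations are \code{ok} up to \code{suspectMm}, \code{suspect} up to
#' \code{failMm} and \code{failed} above it (boundary values take the lower
#' status). Suspect and failed cases are listed so their schedules can be
#' re-tuned manually; they are never retried automatically.
#'
#' @param reports either a numeric vector of errors (mm), a data.frame with
#'   an \code{error_mm} column (extra id columns such as \code{roi},
#'   \code{frame_from}, \code{frame_to} are carried through), or a list of
#'   [PairRegistration-class] objects.
#' @param suspectMm,failMm thresholds in mm, \code{0 < suspectMm <= failMm};
#'   defaults 1 and 2.
#' @return A list with \code{reports} (data.frame with a \code{status}
#'   column), \code{counts} (named ok/suspect/failed totals) and
#'   \code{flagged} (the non-ok subset).
#' @examples
#' classifyRun(c(0.5, 1.5, 2500))$counts
#' @export
classifyRun <- function(reports, suspectMm = 1, failMm = 2) {
  if (!(suspectMm > 0 && suspectMm <= failMm))
    stop("need 0 < suspectMm <= failMm")
  if (is.numeric(reports))
    reports <- data.frame(error_mm = as.numeric(reports))
  if (is.list(reports) && !is.data.frame(reports) &&
      all(vapply(reports, is, logical(1), "PairRegistration")))
    reports <- do.call(rbind, lapply(reports, function(r)
      data.frame(roi = r@roi, frame_from = r@framePair[1L],
                 frame_to = r@framePair[2L], error_mm = r@errorMm)))
  if (!is.data.frame(reports) || !"error_mm" %in% names(reports))
    stop("reports must carry registration errors in an 'error_mm' column")
  e <- reports$error_mm
  status <- ifelse(e > failMm, "failed",
                   ifelse(e > suspectMm, "suspect", "ok"))
  reports$status <- status
  counts <- c(ok = sum(status == "ok"), suspect = sum(status == "suspect"),
              failed = sum(status == "failed"))
  list(reports = reports, counts = counts,
       flagged = reports[status != "ok", , drop = FALSE])
}
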