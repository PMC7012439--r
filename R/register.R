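#' Register one contour onto another in physical coordinates
#'
#' Full consecutive-frame registration pipeline for a single ROI pair:
#' both contours are resampled to uniform arc-length spacing tied to the
#' image resolution ([resampleContour()]), mapped into a shared unit box
#' ([toUnitBox()] with the union bounding box), matched with the modified
#' TPS-RPM matcher ([annealRegister()]), and the recovered transform is
#' conjugated back to mm coordinates ([rescaleTransform()]). The deformed
#' source contour is then compared with the target contour
#' ([registrationError()]) and the result is flagged \code{ok},
#' \code{suspect} or \code{failed}; a poor registration is reported, never
#' raised as an error, so batch runs can continue.
#'
#' @param source,target [PointSet-class] contours in mm (source = earlier
#'   frame, target = later frame).
#' @param spacing resampling spacing in mm; default 1 mm (the in-plane pixel
#'   size).
#' @param schedule an [AnnealingSchedule-class].
#' @param suspectMm,failMm validation thresholds in mm; defaults 1 and 2
#'   (registrations are expected to be accurate to about a millimetre, and
#'   difficult cases to about two).
#' @param roi optional ROI label carried into the result.
#' @param framePair optional (from, to) frame indices carried into the
#'   result.
#' @return A [PairRegistration-class]; its \code{transform} maps mm to mm.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 73)[-73]
#' src <- pointSet(cbind(15 * cos(th), 10 * sin(th)))
#' tgt <- pointSet(cbind(15 * cos(th), 5 + 10 * sin(th)))  # 5 mm superior
#' reg <- registerPair(src, tgt)
#' reg
#' @export
registerPair <- function(source, target, spacing = 1,
                         schedule = annealingSchedule(),
                         suspectMm = 1, failMm = 2,
                         roi = "", framePair = c(NA_integer_, NA_integer_)) {
  stopifnot(is(source, "PointSet"), is(target, "PointSet"))
  rs <- resampleContour(source, spacing)
  rt <- resampleContour(target, spacing)
  sc <- unitBoxScaling(list(rs, rt))
  us <- toUnitBox(rs, sc)$points
  ut <- toUnitBox(rt, sc)$points

  fit <- annealRegister(us, ut, schedule,
                        tFinal = schedule@tFinalFactor *
                          (spacing / sc@scale)^2)
  tfMm <- rescaleTransform(fit$transform, sc)
  deformed <- transformPoints(tfMm, rs)
  err <- registrationError(deformed, rt)
  status <- if (err > failMm) "failed" else if (err > suspectMm) "suspect"
            else "ok"

  new("PairRegistration", roi = as.character(roi),
      framePair = as.integer(framePair), transform = tfMm,
      errorMm = err, status = status,
      diagnostics = list(trace = fit$diagnostics, scaling = sc,
                         nSource = nPoints(rs), nTarget = nPoints(rt),
                         outerIterations = nrow(fit$diagnostics)))
}

#' Register every consecutive frame pair of a contour sequence
#'
#' Applies [registerPair()] to frames (1, 2), (2, 3), ..., (n-1, n) of one
#' ROI's [ContourSequence-class], as done when processing a full cine scan.
#'
#' @param seq a [ContourSequence-class].
#' @param spacing,schedule,suspectMm,failMm passed to [registerPair()].
#' @param verbose emit one structured log line per registration (ROI, frame
#'   pair, iterations, final error) to \code{stderr}.
#' @return A list of [PairRegistration-class] objects of length
#'   \code{nFrames(seq) - 1}.
#' @export
registerSequence <- function(seq, spacing = 1,
                             schedule = annealingSchedule(),
                             suspectMm = 1, failMm = 2, verbose = FALSE) {
  stopifnot(is(seq, "ContourSequence"))
  fr <- frames(seq)
  idx <- frameIndices(seq)
  out <- vector("list", length(fr) - 1L)
  for (k in seq_along(out)) {
    t0 <- proc.time()[["elapsed"]]
    reg <- registerPair(fr[[k]], fr[[k + 1L]], spacing = spacing,
                        schedule = schedule, suspectMm = suspectMm,
                        failMm = failMm, roi = roiName(seq),
                        framePair = idx[k + 0:1])
    if (verbose)
      .logLine("info",
               "roi=%s frames=%d->%d iters=%d error_mm=%.4f status=%s elapsed_s=%.2f",
               roiName(seq), idx[k], idx[k + 1L],
               reg@diagnostics$outerIterations, reg@errorMm, reg@status,
               proc.time()[["elapsed"]] - t0)
    out[[k]] <- reg
  }
  out
}
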