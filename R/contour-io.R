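#' Read a contour sequence from JSON or CSV
#'
#' Reads one ROI's per-frame contours from either the package's JSON schema
#' or a flat CSV dialect and returns a validated [ContourSequence-class].
#' Coordinates stored in pixel units (schema flag \code{units = "pixel"}, or
#' the \code{units} argument for CSV) are converted to mm with the pixel
#' spacing at read time; all downstream processing operates in physical
#' units.
#'
#' \strong{JSON schema} (one object per ROI): \preformatted{
#' {"roi": "...", "pixel_spacing": [dr, dc], "frame_interval_ms": 160,
#'  "units": "mm" | "pixel",
#'  "frames": [{"index": 1, "points": [[x, y], ...]}, ...]}
#' }
#' \strong{CSV dialect}: header \code{roi,frame,point_index,x,y}; one contour
#' is the block of rows sharing (roi, frame), ordered by \code{point_index}.
#' CSV carries no metadata, so pixel spacing, frame interval and units come
#' from the arguments.
#'
#' Pixel-to-mm conversion multiplies x by the column spacing and y by the row
#' spacing. Image row indices grow inferiorly while the package's mm frame
#' has +y superior; pixel-unit inputs whose y is a raw row index should pass
#' \code{flipRows} (the image matrix height) so y is re-expressed as
#' \code{flipRows - 1 - row} before scaling.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"json"} or \code{"csv"}.
#' @param pixelSpacing mm per pixel (row, column); CSV only (JSON carries its
#'   own). Default \code{c(1, 1)}.
#' @param frameIntervalMs frame interval in ms; CSV only. Default 160.
#' @param units \code{"mm"} or \code{"pixel"}; CSV only.
#' @param flipRows optional image height (rows) used to flip pixel-row y
#'   coordinates into the +y-superior mm frame.
#' @return A [ContourSequence-class].
#' @seealso [writeContourSequence()]
#' @export
readContourSequence <- function(path, format = c("auto", "json", "csv"),
                                pixelSpacing = c(1, 1), frameIntervalMs = 160,
                                units = c("mm", "pixel"), flipRows = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("contour file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"

  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed contour JSON in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    for (fld in c("roi", "pixel_spacing", "frames"))
      if (is.null(obj[[fld]]))
        stop(sprintf("contour JSON %s: missing required field '%s'",
                     path, fld))
    roi <- as.character(obj$roi)
    spacing <- as.numeric(unlist(obj$pixel_spacing))
    interval <- if (is.null(obj$frame_interval_ms)) 160
                else as.numeric(obj$frame_interval_ms)
    units <- if (is.null(obj$units)) "mm" else as.character(obj$units)
    idx <- integer(0)
    pts <- list()
    for (k in seq_along(obj$frames)) {
      fr <- obj$frames[[k]]
      if (is.null(fr$index) || is.null(fr$points))
        stop(sprintf("contour JSON %s: frame record %d lacks index/points",
                     path, k))
      m <- do.call(rbind, lapply(fr$points, function(p) {
        p <- as.numeric(unlist(p))
        if (length(p) != 2L || any(!is.finite(p)))
          stop(sprintf("contour JSON %s: frame %s has a malformed point",
                       path, fr$index), call. = FALSE)
        p
      }))
      if (is.null(m) || nrow(m) < 3L)
        stop(sprintf("contour JSON %s: frame %s has fewer than 3 points",
                     path, fr$index))
      idx[k] <- as.integer(fr$index)
      pts[[k]] <- m
    }
  } else {
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e)
                     stop("malformed contour CSV in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    need <- c("roi", "frame", "point_index", "x", "y")
    if (!all(need %in% names(df)))
      stop("contour CSV ", path, " must have columns ",
           paste(need, collapse = ","))
    if (length(unique(df$roi)) != 1L)
      stop("contour CSV ", path, " must describe exactly one ROI")
    roi <- df$roi[1L]
    spacing <- as.numeric(pixelSpacing)
    interval <- frameIntervalMs
    units <- match.arg(units)
    idx <- sort(unique(as.integer(df$frame)))
    pts <- lapply(idx, function(fi) {
      blk <- df[df$frame == fi, , drop = FALSE]
      blk <- blk[order(blk$point_index), , drop = FALSE]
      m <- cbind(as.numeric(blk$x), as.numeric(blk$y))
      if (nrow(m) < 3L || any(!is.finite(m)))
        stop(sprintf("contour CSV %s: frame %d has fewer than 3 valid points",
                     path, fi), call. = FALSE)
      m
    })
  }

  if (!units %in% c("mm", "pixel"))
    stop("units must be 'mm' or 'pixel', got '", units, "'")
  if (units == "pixel") {
    pts <- lapply(pts, function(m) {
      if (!is.null(flipRows)) m[, 2L] <- flipRows - 1 - m[, 2L]
      cbind(m[, 1L] * spacing[2L], m[, 2L] * spacing[1L])
    })
  }
  contourSequence(roi, lapply(pts, pointSet), pixelSpacing = spacing,
                  frameInterval = interval, frameIndices = idx)
}

#' Write a contour sequence to JSON or CSV
#'
#' Inverse of [readContourSequence()]; coordinates are always written in mm
#' at full precision, so write-then-read reproduces the sequence exactly.
#'
#' @param seq a [ContourSequence-class].
#' @param path output file.
#' @param format \code{"auto"} (by extension), \code{"json"} or \code{"csv"}.
#' @return Invisibly, \code{path}.
#' @export
writeContourSequence <- function(seq, path, format = c("auto", "json", "csv")) {
  stopifnot(is(seq, "ContourSequence"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    obj <- list(
      roi = jsonlite::unbox(roiName(seq)),
      pixel_spacing = pixelSpacing(seq),
      frame_interval_ms = jsonlite::unbox(frameInterval(seq)),
      units = jsonlite::unbox("mm"),
      frames = Map(function(i, f)
        list(index = jsonlite::unbox(i), points = unname(coords(f))),
        frameIndices(seq), frames(seq)))
    jsonlite::write_json(obj, path, digits = NA)
  } else {
    rows <- Map(function(i, f) {
      m <- coords(f)
      data.frame(roi = roiName(seq), frame = i,
                 point_index = seq_len(nrow(m)), x = m[, 1L], y = m[, 2L])
    }, frameIndices(seq), frames(seq))
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a motion table to CSV
#'
#' One row per (frame, direction) plus four summary rows with
#' \code{frame = "max"}; columns \code{roi,frame,direction,magnitude_mm}.
#'
#' @param table a [MotionTable-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @seealso [readMotionTable()]
#' @export
writeMotionTable <- function(table, path) {
  stopifnot(is(table, "MotionTable"))
  pf <- perFrameMotion(table)
  long <- do.call(rbind, lapply(seq_len(nrow(pf)), function(i)
    data.frame(roi = roiName(table), frame = as.character(pf$frame[i]),
               direction = .DIRECTIONS,
               magnitude_mm = as.numeric(pf[i, .DIRECTIONS]))))
  long <- rbind(long,
                data.frame(roi = roiName(table), frame = "max",
                           direction = .DIRECTIONS,
                           magnitude_mm = as.numeric(motionSummary(table))))
  # full precision so round trips are exact to numerical tolerance
  long$magnitude_mm <- formatC(long$magnitude_mm, format = "g", digits = 17)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion table written by [writeMotionTable()]
#'
#' @param path CSV file path.
#' @return A [MotionTable-class].
#' @export
readMotionTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(frame = "character"))
  need <- c("roi", "frame", "direction", "magnitude_mm")
  if (!all(need %in% names(df)))
    stop("motion CSV ", path, " must have columns ",
         paste(need, collapse = ","))
  smry <- df[df$frame == "max", , drop = FALSE]
  pf <- df[df$frame != "max", , drop = FALSE]
  frames <- unique(as.integer(pf$frame))
  wide <- data.frame(frame = frames)
  for (d in .DIRECTIONS)
    wide[[d]] <- vapply(frames, function(f)
      pf$magnitude_mm[pf$frame == as.character(f) & pf$direction == d][1L],
      numeric(1))
  summary <- setNames(vapply(.DIRECTIONS, function(d)
    smry$magnitude_mm[smry$direction == d][1L], numeric(1)), .DIRECTIONS)
  motionTable(df$roi[1L], wide, summary = summary)
}
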