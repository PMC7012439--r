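.defaultConfig <- function() {
  list(input = ".", outdir = "cinemotion_out", spacing_mm = 1, margin_mm = 2,
       suspect_mm = 1, fail_mm = 2, log_level = "info",
       schedule = list())
}

#' Load a batch run configuration
#'
#' Reads a YAML or JSON configuration file and merges it over the package
#' defaults. Recognised keys: \code{input} (directory or vector of contour
#' files), \code{outdir}, \code{spacing_mm}, \code{margin_mm},
#' \code{suspect_mm}, \code{fail_mm}, \code{log_level} and a \code{schedule}
#' block whose entries are passed to [annealingSchedule()]
#' (\code{t_init_factor}, \code{t_final_factor}, \code{rate},
#' \code{inner_iters}, \code{lambda_init}, \code{outlier_t_policy},
#' \code{sinkhorn_tol}, \code{sinkhorn_max_sweeps}).
#'
#' @param path YAML/JSON file, or \code{NULL} for pure defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return A configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg
}

.scheduleFromConfig <- function(sc) {
  if (is.null(sc) || !length(sc)) return(annealingSchedule())
  annealingSchedule(
    tInitFactor = sc$t_init_factor %||% 1,
    tFinalFactor = sc$t_final_factor %||% 0.04,
    rate = sc$rate %||% 0.93,
    innerIters = sc$inner_iters %||% 3L,
    lambdaInit = sc$lambda_init %||% 1,
    lambda2Init = sc$lambda2_init %||% 0.01,
    outlierTPolicy = sc$outlier_t_policy %||% "t-init",
    sinkhornTol = sc$sinkhorn_tol %||% 1e-3,
    sinkhornMaxSweeps = sc$sinkhorn_max_sweeps %||% 30L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch-process contour sequences without interaction
#'
#' Reproduces the unattended batch workflow: every contour file found in the
#' configured input is read, all consecutive frame pairs of each ROI are
#' registered, each ROI's motion time course is estimated and written to
#' CSV, and all registrations are validated and classified. A failed or
#' suspect registration is flagged in the report but never aborts the batch,
#' and a corrupted input file is skipped with an error logged while the
#' remaining files complete. The numerical core is deterministic, so
#' re-running an identical configuration reproduces the motion CSVs
#' byte-for-byte.
#'
#' Outputs written to \code{outdir}: \code{<roi>_motion.csv} per ROI
#' ([writeMotionTable()] format), \code{report.csv} (one row per
#' registration: \code{roi,frame_from,frame_to,error_mm,status}) and
#' \code{summary.json} (status counts and skipped files).
#'
#' @param config a configuration list ([readRunConfig()]), or a path to a
#'   YAML/JSON config file.
#' @return Invisibly, a list with \code{counts}, \code{reports},
#'   \code{tables}, \code{skipped} and \code{status} (0 when every file was
#'   processed, 1 when any was skipped).
#' @export
runBatch <- function(config = readRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  lvl <- config$log_level %||% "info"
  schedule <- .scheduleFromConfig(config$schedule)

  files <- config$input
  if (length(files) == 1L && dir.exists(files))
    files <- list.files(files, pattern = "\\.(json|csv)$", full.names = TRUE)
  files <- sort(files)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  reportRows <- list()
  tables <- list()
  skipped <- character(0)
  for (f in files) {
    seq <- tryCatch(readContourSequence(f), error = function(e) {
      .logLine("error", "skipping %s: %s", f, conditionMessage(e),
               minLevel = lvl)
      NULL
    })
    if (is.null(seq)) {
      skipped <- c(skipped, f)
      next
    }
    .logLine("info", "roi=%s file=%s frames=%d", roiName(seq), basename(f),
             nFrames(seq), minLevel = lvl)
    regs <- registerSequence(seq, spacing = config$spacing_mm,
                             schedule = schedule,
                             suspectMm = config$suspect_mm,
                             failMm = config$fail_mm,
                             verbose = lvl == "debug")
    for (r in regs)
      reportRows[[length(reportRows) + 1L]] <-
        data.frame(roi = r@roi, frame_from = r@framePair[1L],
                   frame_to = r@framePair[2L], error_mm = r@errorMm)
    tab <- motionTimecourse(seq, regs, gridSpacing = config$spacing_mm,
                            margin = config$margin_mm)
    tables[[roiName(seq)]] <- tab
    writeMotionTable(tab, file.path(config$outdir,
                                    paste0(roiName(seq), "_motion.csv")))
  }

  if (length(reportRows)) {
    cls <- classifyRun(do.call(rbind, reportRows),
                       suspectMm = config$suspect_mm,
                       failMm = config$fail_mm)
    reports <- cls$reports
    counts <- cls$counts
  } else {
    reports <- data.frame(roi = character(0), frame_from = integer(0),
                          frame_to = integer(0), error_mm = numeric(0),
                          status = character(0))
    counts <- c(ok = 0L, suspect = 0L, failed = 0L)
  }
  write.csv(reports, file.path(config$outdir, "report.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_files = length(files), n_registrations = nrow(reports),
         counts = as.list(counts), skipped = skipped),
    file.path(config$outdir, "summary.json"), auto_unbox = TRUE)
  .logLine("info", "done: %d registrations (%d ok, %d suspect, %d failed)",
           nrow(reports), counts[["ok"]], counts[["suspect"]],
           counts[["failed"]], minLevel = lvl)
  invisible(list(counts = counts, reports = reports, tables = tables,
                 skipped = skipped,
                 status = if (length(skipped)) 1L else 0L))
}

#' Write a synthetic scene to contour files
#'
#' Emits the contour JSON of each ROI of a synthetic scene into a directory,
#' ready for [runBatch()]; the ground-truth motion CSVs are placed in a
#' \code{truth/} subdirectory so they are not mistaken for contour inputs.
#'
#' @param specs list of [SyntheticSpec-class], e.g.
#'   [defaultSwallowScene()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the written contour file paths.
#' @export
simulateScene <- function(specs, outdir) {
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE,
             recursive = TRUE)
  paths <- vapply(specs, function(sp) {
    gen <- generateSequence(sp)
    p <- file.path(outdir, paste0(sp@roi, ".json"))
    writeContourSequence(gen$sequence, p)
    writeMotionTable(gen$truth,
                     file.path(outdir, "truth", paste0(sp@roi, "_truth.csv")))
    p
  }, character(1))
  invisible(paths)
}
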