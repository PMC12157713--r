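# CSV I/O for measurements, calibration series, cohorts and pressure traces.
#
# Measurement layout: comment-prefixed header lines (`# key=value`), then a
# `time_s,<channel>,...` table. The sampling rate is stored explicitly so
# downstream code never assumes one.

.parseError <- function(...) {
  stop(errorCondition(paste0(...), class = c("septanose_parse_error", "error")))
}

.fmtNum <- function(x) sprintf("%.10g", x)

#' Write one e-Nose measurement to CSV
#'
#' Deterministic, byte-stable output: two writes of the same measurement give
#' identical files. The inverse of \code{\link{readMeasurement}}.
#'
#' @param m an \linkS4class{ENoseMeasurement}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMeasurement <- function(m, path) {
  validObject(m)
  cv <- m@curves
  t <- cv[[1]]@times
  rate <- 1 / (t[2] - t[1])
  hdr <- c("# septanose measurement v1",
           paste0("# animal_id=", m@animalId),
           paste0("# group=", m@group),
           paste0("# timepoint=", m@timepoint),
           paste0("# fio2=", .fmtNum(m@fio2)),
           paste0("# rate_hz=", .fmtNum(rate)),
           paste0("# phase_bounds_s=", paste(.fmtNum(cv[[1]]@phaseBounds), collapse = ",")))
  mat <- vapply(cv, function(x) x@resistance, numeric(length(t)))
  rows <- apply(cbind(t, mat), 1L, function(r) paste(.fmtNum(r), collapse = ","))
  writeLines(c(hdr, paste(c("time_s", names(cv)), collapse = ","), rows), path)
  invisible(path)
}

#' Read one e-Nose measurement from CSV
#'
#' Validates the file against every measurement invariant (uniform strictly
#' increasing time grid, strictly positive resistance, unique channels) and
#' raises a typed parse error (\code{septanose_parse_error}) naming the first
#' violation.
#'
#' @param path file written by \code{\link{writeMeasurement}}.
#' @return An \linkS4class{ENoseMeasurement}.
#' @export
readMeasurement <- function(path) {
  if (!file.exists(path)) .parseError("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# *([a-z0-9_]+)=(.*)$", hdr))
  kv <- Filter(function(x) length(x) == 3L, kv)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                          vapply(kv, `[`, character(1), 2L))
  for (k in c("animal_id", "group", "timepoint", "fio2", "phase_bounds_s"))
    if (!k %in% names(meta)) .parseError("malformed header: missing '", k, "'")
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 3L) .parseError("malformed file: fewer than 2 data rows")
  df <- utils::read.csv(text = paste(body, collapse = "\n"), check.names = FALSE)
  if (names(df)[1] != "time_s" || ncol(df) < 2L)
    .parseError("malformed header row: expected time_s plus >= 1 channel column")
  t <- df[[1]]
  g <- .checkUniformGrid(t)
  if (!is.null(g)) .parseError("invalid time grid: ", g)
  pb <- as.numeric(strsplit(meta[["phase_bounds_s"]], ",")[[1]])
  if (length(pb) != 3L || any(!is.finite(pb)))
    .parseError("malformed phase_bounds_s header")
  curves <- lapply(names(df)[-1], function(ch) {
    r <- df[[ch]]
    if (any(!is.finite(r)) || any(r <= 0))
      .parseError("channel ", ch, " violates the positivity invariant: ",
                  "all resistance values must be > 0")
    sensorCurve(ch, t, r, pb)
  })
  m <- try(eNoseMeasurement(meta[["animal_id"]], meta[["group"]],
                            meta[["timepoint"]], as.numeric(meta[["fio2"]]),
                            curves), silent = TRUE)
  if (inherits(m, "try-error"))
    .parseError("invalid measurement: ", attr(m, "condition")$message)
  m
}

#' Extract one protocol phase from a sensor curve
#'
#' Phases partition the time axis: "before" covers [0, before_end), "during"
#' [before_end, during_end), "after" [during_end, total]. Times are preserved,
#' not re-zeroed, so concatenating the three slices reproduces the original
#' curve sample-for-sample.
#'
#' @param c a \linkS4class{SensorCurve}.
#' @param phase \code{"before"}, \code{"during"} or \code{"after"}.
#' @return A \linkS4class{SensorCurve} restricted to the phase.
#' @export
slicePhase <- function(c, phase) {
  pb <- c@phaseBounds
  idx <- switch(phase,
    before = c@times < pb[1],
    during = c@times >= pb[1] & c@times < pb[2],
    after  = c@times >= pb[2],
    stop("unknown phase label: '", phase, "'"))
  sensorCurve(c@channelId, c@times[idx], c@resistance[idx], pb)
}

# ---- cohort / calibration directories --------------------------------------

#' Write a set of measurements plus a cohort manifest
#'
#' @param measurements list of \linkS4class{ENoseMeasurement}.
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(measurements, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(measurements, function(m) {
    fn <- sprintf("%s_%s.csv", m@animalId, m@timepoint)
    writeMeasurement(m, file.path(dir, fn))
    data.frame(path = fn, animal_id = m@animalId, group = m@group,
               timepoint = m@timepoint, fio2 = m@fio2)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a cohort of measurements from a manifest
#'
#' @param manifestPath path of a manifest CSV written by \code{\link{writeCohort}}.
#' @return List of \linkS4class{ENoseMeasurement}.
#' @export
readCohort <- function(manifestPath) {
  manifest <- utils::read.csv(manifestPath)
  dir <- dirname(manifestPath)
  lapply(manifest$path, function(p) readMeasurement(file.path(dir, p)))
}

#' Write / read a calibration series as a measurement directory
#'
#' Serializes each replicate at each FiO2 level as one measurement CSV plus a
#' calibration manifest recording level and replicate index.
#'
#' @param cs a \linkS4class{CalibrationSeries}.
#' @param dir directory.
#' @return \code{writeCalibrationSeries}: the manifest path, invisibly;
#'   \code{readCalibrationSeries}: a \linkS4class{CalibrationSeries}.
#' @export
writeCalibrationSeries <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(cs@levels)) {
    for (j in seq_along(cs@replicates[[i]])) {
      m <- cs@replicates[[i]][[j]]
      fn <- sprintf("cal_fio2_%03.0f_r%d.csv", 1000 * cs@levels[i], j)
      writeMeasurement(m, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(path = fn, level = cs@levels[i],
                                              replicate = j)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "cal_manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' @rdname writeCalibrationSeries
#' @param manifestPath path of a calibration manifest CSV.
#' @export
readCalibrationSeries <- function(manifestPath) {
  manifest <- utils::read.csv(manifestPath)
  dir <- dirname(manifestPath)
  levels <- sort(unique(manifest$level))
  reps <- lapply(levels, function(lv) {
    sub <- manifest[abs(manifest$level - lv) < 1e-9, , drop = FALSE]
    sub <- sub[order(sub$replicate), , drop = FALSE]
    lapply(sub$path, function(p) readMeasurement(file.path(dir, p)))
  })
  calibrationSeries(levels, reps)
}

# ---- pressure traces -------------------------------------------------------

#' Write / read a ventilator pressure trace CSV
#'
#' Format: `time_s,pressure_cmh2o` with a `# threshold_cmh2o=` header line.
#'
#' @param p a \linkS4class{PressureTrace}.
#' @param path file path.
#' @return The path (write) or a \linkS4class{PressureTrace} (read).
#' @export
writePressureTrace <- function(p, path) {
  writeLines(c(paste0("# threshold_cmh2o=", .fmtNum(p@threshold)),
               "time_s,pressure_cmh2o",
               paste(.fmtNum(p@times), .fmtNum(p@pressure), sep = ",")),
             path)
  invisible(path)
}

#' @rdname writePressureTrace
#' @export
readPressureTrace <- function(path) {
  lines <- readLines(path)
  thr <- as.numeric(sub("^# *threshold_cmh2o=", "",
                        grep("^# *threshold_cmh2o=", lines, value = TRUE)[1]))
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  pressureTrace(df$time_s, df$pressure_cmh2o, thr)
}
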