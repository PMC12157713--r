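# FiO2 correction: build bivariate k(t, FiO2) surfaces from a clean-air
# calibration series and apply them to baseline-removed sample curves.
#
# Two strategies:
#   diff : k_diff(t, f) = M(t, f) - M(t, 0.21), applied subtractively to
#          subtract-baseline-removed samples;
#   ratio: k_ratio(t, f) = M(t, f) / M(t, 0.21), applied by division to
#          divide-baseline-removed samples;
# with M the per-level mean calibration curve. By default the calibration
# mean curves are themselves baseline-removed with the strategy's own mode
# before differencing/ratioing, keeping k in the same units as the sample
# curves it corrects (the `raw` calibration mode is available for the
# literal uncorrected-units construction).

#' Pointwise mean calibration curve at one FiO2 level
#'
#' Arithmetic mean across the replicate clean-air curves of one channel at
#' one level: M(t, f) = (1/n) sum_i R_i(t, f).
#'
#' @param cs a \linkS4class{CalibrationSeries}.
#' @param channel channel id.
#' @param level FiO2 level (must be one of the series' levels).
#' @return A \linkS4class{SensorCurve} holding the mean curve.
#' @export
meanLevelCurve <- function(cs, channel, level) {
  reps <- calibrationReplicates(cs, level)
  curves <- lapply(reps, function(m) {
    if (!channel %in% names(m@curves))
      stop("channel ", channel, " absent from a calibration replicate")
    m@curves[[channel]]
  })
  ref <- curves[[1]]
  for (x in curves[-1]) {
    if (!isTRUE(all.equal(x@times, ref@times)))
      stop("calibration replicates have mismatched time grids")
  }
  avg <- Reduce(`+`, lapply(curves, function(x) x@resistance)) / length(curves)
  sensorCurve(channel, ref@times, avg, ref@phaseBounds)
}

#' Remove the baseline from a sensor curve
#'
#' Subtract mode: R(t) - R(0) (first value becomes exactly 0). Divide mode:
#' R(t) / R(0) (first value becomes exactly 1).
#'
#' @param c a \linkS4class{SensorCurve}.
#' @param mode \code{"subtract"} or \code{"divide"}.
#' @return A curve-like object: same class layout as \linkS4class{SensorCurve}
#'   but with the baseline-removed values in the resistance slot (these may be
#'   zero or negative, so the object is built without the positivity check).
#' @export
removeBaseline <- function(c, mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  r0 <- c@resistance[1]
  v <- if (mode == "subtract") c@resistance - r0 else {
    if (r0 <= 0) stop("zero or negative baseline value under divide mode")
    c@resistance / r0
  }
  # bypass the positivity validity check: baseline-removed values are signed
  out <- c
  out@resistance <- v
  attr(out@resistance, "baselineMode") <- mode
  out
}

.baselineModeOf <- function(c) {
  m <- attr(c@resistance, "baselineMode")
  if (!is.null(m)) return(m)
  v1 <- c@resistance[1]
  if (abs(v1) < 1e-9) "subtract" else if (abs(v1 - 1) < 1e-9) "divide" else NA_character_
}

#' Build a correction surface from a calibration series
#'
#' For each calibration level the per-level mean curve is computed
#' (\code{\link{meanLevelCurve}}), optionally baseline-removed with the
#' strategy's own mode (\code{baselineMode = "matched"}, the default), and
#' differenced (diff) or ratioed (ratio) against the 21 % reference curve.
#' At the reference level the surface is exactly 0 (diff) or 1 (ratio) by
#' construction.
#'
#' @param cs a \linkS4class{CalibrationSeries}.
#' @param channel channel id.
#' @param strategy \code{"diff"} or \code{"ratio"}.
#' @param baselineMode \code{"matched"} (default) or \code{"raw"}.
#' @return A \linkS4class{CorrectionSurface}.
#' @export
buildSurface <- function(cs, channel, strategy = c("diff", "ratio"),
                         baselineMode = c("matched", "raw")) {
  strategy <- match.arg(strategy)
  baselineMode <- match.arg(baselineMode)
  validObject(cs)
  means <- lapply(cs@levels, function(lv) meanLevelCurve(cs, channel, lv))
  if (baselineMode == "matched") {
    bmode <- if (strategy == "diff") "subtract" else "divide"
    means <- lapply(means, removeBaseline, mode = bmode)
  }
  times <- means[[1]]@times
  iref <- which(abs(cs@levels - REFERENCE_FIO2) < 1e-9)
  refv <- means[[iref]]@resistance
  k <- vapply(means, function(m) {
    if (strategy == "diff") m@resistance - refv
    else {
      if (any(refv <= 0) || any(m@resistance <= 0))
        stop("zero or negative mean calibration curve under ratio strategy")
      m@resistance / refv
    }
  }, numeric(length(times)))
  # exact reference identity at grid nodes
  k[, iref] <- if (strategy == "ratio") 1 else 0
  new("CorrectionSurface", channelId = channel, strategy = strategy,
      gridTimes = as.numeric(times), gridLevels = cs@levels, kValues = k,
      referenceLevel = REFERENCE_FIO2, baselineMode = baselineMode)
}

#' Evaluate a correction surface
#'
#' Bilinear interpolation inside the (time x FiO2) grid hull. FiO2 outside
#' the calibrated level range is clamped to the nearest level with a warning;
#' times outside the calibration grid are an error.
#'
#' @param k a \linkS4class{CorrectionSurface}.
#' @param t time(s) in seconds (vectorised).
#' @param fio2 a single FiO2 fraction.
#' @return Numeric correction values, one per element of \code{t}.
#' @export
evaluateSurface <- function(k, t, fio2) {
  gt <- k@gridTimes; gl <- k@gridLevels
  if (any(t < min(gt) - 1e-9) || any(t > max(gt) + 1e-9))
    stop("time outside the calibration grid [", min(gt), ", ", max(gt), "] s")
  if (fio2 < min(gl) - 1e-12 || fio2 > max(gl) + 1e-12) {
    clamped <- min(max(fio2, min(gl)), max(gl))
    warning(sprintf("FiO2 %.3f outside calibrated range [%.2f, %.2f]; clamped to %.2f",
                    fio2, min(gl), max(gl), clamped))
    fio2 <- clamped
  }
  j <- findInterval(fio2, gl, all.inside = TRUE)
  w <- (fio2 - gl[j]) / (gl[j + 1] - gl[j])
  colj <- stats::approx(gt, k@kValues[, j], xout = t)$y
  colj1 <- stats::approx(gt, k@kValues[, j + 1], xout = t)$y
  (1 - w) * colj + w * colj1
}

#' Apply an FiO2 correction to a baseline-removed sample curve
#'
#' diff strategy: R_corr(t) = R_bas(t) - k_diff(t, fio2), with R_bas the
#' subtract-baseline-removed curve. ratio strategy: R_corr(t) =
#' R_bas(t) / k_ratio(t, fio2), with R_bas divide-baseline-removed. The
#' curve's baseline-removal mode must match the surface strategy. The surface
#' is resampled (linearly in t) to the sample grid; the sample is never
#' resampled. At the 0.21 reference the correction is the identity map.
#'
#' @param c a baseline-removed curve (\code{\link{removeBaseline}}).
#' @param k a \linkS4class{CorrectionSurface} for the same channel.
#' @param fio2 FiO2 of the analysed sample.
#' @return The corrected curve (same layout as the input).
#' @export
applyCorrection <- function(c, k, fio2) {
  bmode <- .baselineModeOf(c)
  want <- if (k@strategy == "diff") "subtract" else "divide"
  if (is.na(bmode) || !identical(bmode, want))
    stop("baseline-removal mode of the curve ('", bmode,
         "') does not match surface strategy '", k@strategy,
         "' (needs '", want, "')")
  kv <- evaluateSurface(k, c@times, fio2)
  out <- c
  if (k@strategy == "diff") {
    out@resistance <- c@resistance - kv
  } else {
    if (any(kv == 0)) stop("ratio correction value of 0")
    out@resistance <- c@resistance / kv
  }
  attr(out@resistance, "baselineMode") <- bmode
  out
}

#' Build correction surfaces for every channel
#'
#' @param cs a \linkS4class{CalibrationSeries}.
#' @param strategy \code{"diff"} or \code{"ratio"}.
#' @param baselineMode passed to \code{\link{buildSurface}}.
#' @return Named list of \linkS4class{CorrectionSurface}, one per channel.
#' @export
buildSurfaces <- function(cs, strategy, baselineMode = "matched") {
  channels <- names(cs@replicates[[1]][[1]]@curves)
  stats::setNames(lapply(channels, buildSurface, cs = cs, strategy = strategy,
                         baselineMode = baselineMode), channels)
}

# ---- surface serialization -------------------------------------------------

#' Write / read correction surfaces
#'
#' Long-format CSV (channel, time_s, fio2, k) plus a JSON sidecar holding the
#' strategy, reference level and calibration baseline mode.
#'
#' @param surfaces named list of \linkS4class{CorrectionSurface}.
#' @param path CSV path (sidecar written next to it as \code{<path>.json}).
#' @return The CSV path (write) or a named surface list (read).
#' @export
writeSurfaces <- function(surfaces, path) {
  long <- do.call(rbind, lapply(surfaces, function(s) {
    data.frame(channel = s@channelId,
               time_s = rep(s@gridTimes, times = length(s@gridLevels)),
               fio2 = rep(s@gridLevels, each = length(s@gridTimes)),
               k = as.vector(s@kValues))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  s1 <- surfaces[[1]]
  jsonlite::write_json(list(strategy = s1@strategy,
                            referenceLevel = s1@referenceLevel,
                            baselineMode = s1@baselineMode),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSurfaces
#' @export
readSurfaces <- function(path) {
  long <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chs <- unique(long$channel)
  stats::setNames(lapply(chs, function(ch) {
    sub <- long[long$channel == ch, ]
    gt <- sort(unique(sub$time_s)); gl <- sort(unique(sub$fio2))
    k <- matrix(NA_real_, length(gt), length(gl))
    k[cbind(match(sub$time_s, gt), match(sub$fio2, gl))] <- sub$k
    new("CorrectionSurface", channelId = ch, strategy = meta$strategy,
        gridTimes = gt, gridLevels = gl, kValues = k,
        referenceLevel = meta$referenceLevel, baselineMode = meta$baselineMode)
  }), chs)
}
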