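#' @import methods
NULL

STUDY_TIMEPOINTS <- c("t0", "t5", "t30", "t60", "t90", "t120", "t150", "t180")
GROUP_LEVELS <- c("control", "LPS", "calibration")
REFERENCE_FIO2 <- 0.21

#' The default eight-channel MOS sensor array
#'
#' Channel identifiers of the sensor chamber: two TGS2603 and two TGS2600
#' units (distinct physical devices, suffixed \code{_a}/\code{_b}) plus one
#' each of TGS2610, TGS2620, TGS2611 and TGS2602.
#'
#' @return Character vector of eight channel ids.
#' @export
defaultChannelIds <- function() {
  c("TGS2603_a", "TGS2603_b", "TGS2600_a", "TGS2600_b",
    "TGS2610", "TGS2620", "TGS2611", "TGS2602")
}

.checkUniformGrid <- function(times, tol = 1e-6) {
  if (length(times) < 2) return("times must have length >= 2")
  d <- diff(times)
  if (any(d <= 0)) return("times must be strictly increasing")
  if (max(d) - min(d) > tol * max(d)) {
    return("times must lie on a uniform grid")
  }
  NULL
}

# ---- SensorCurve -----------------------------------------------------------

#' SensorCurve: one channel's resistance time series
#'
#' Holds the resistance response of a single MOS channel over the three-phase
#' measurement protocol: "before" (clean reference air, baseline), "during"
#' (sample drawn through the chamber) and "after" (recovery in clean air).
#' Phase boundaries are stored per curve as \code{(before_end, during_end,
#' total)} seconds; the default \code{c(60, 360, 960)} corresponds to
#' 1 min / 5 min / 10 min.
#'
#' @slot channelId single channel identifier.
#' @slot times seconds from analysis start; strictly increasing, uniform grid.
#' @slot resistance sensor resistance in ohms, strictly positive.
#' @slot phaseBounds numeric length-3: before-end, during-end, total seconds.
#' @export
setClass("SensorCurve",
  representation(channelId = "character", times = "numeric",
                 resistance = "numeric", phaseBounds = "numeric"))

setValidity("SensorCurve", function(object) {
  msgs <- character()
  if (length(object@channelId) != 1L || !nzchar(object@channelId))
    msgs <- c(msgs, "channelId must be a single non-empty string")
  if (length(object@times) != length(object@resistance))
    msgs <- c(msgs, "times and resistance must have equal length")
  g <- .checkUniformGrid(object@times)
  if (!is.null(g)) msgs <- c(msgs, g)
  if (any(!is.finite(object@resistance)) || any(object@resistance <= 0))
    msgs <- c(msgs, "all resistance values must be finite and > 0")
  pb <- object@phaseBounds
  if (length(pb) != 3L || any(!is.finite(pb)) || !(pb[1] < pb[2] && pb[2] < pb[3]) || pb[1] <= 0)
    msgs <- c(msgs, "phaseBounds must be (before_end, during_end, total) with 0 < before_end < during_end < total")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SensorCurve
#'
#' @param channelId channel identifier, e.g. \code{"TGS2603_a"}.
#' @param times seconds from analysis start (uniform, strictly increasing).
#' @param resistance resistance values in ohms (> 0).
#' @param phaseBounds phase boundaries in seconds; default \code{c(60, 360, 960)}.
#' @return A validated \linkS4class{SensorCurve}.
#' @export
sensorCurve <- function(channelId, times, resistance,
                        phaseBounds = c(60, 360, 960)) {
  new("SensorCurve", channelId = as.character(channelId),
      times = as.numeric(times), resistance = as.numeric(resistance),
      phaseBounds = as.numeric(phaseBounds))
}

# ---- ENoseMeasurement ------------------------------------------------------

#' ENoseMeasurement: one e-Nose analysis of one breath (or clean-air) sample
#'
#' Bundles one \linkS4class{SensorCurve} per channel with the acquisition
#' metadata: animal id, group (control / LPS / calibration), study timepoint
#' and the inspired-oxygen fraction (FiO2) the sample was collected at. All
#' curves must share the same time grid and phase boundaries.
#'
#' @slot animalId subject identifier.
#' @slot group one of \code{"control"}, \code{"LPS"}, \code{"calibration"}.
#' @slot timepoint study timepoint label (\code{t0} ... \code{t180}) or a
#'   calibration tag.
#' @slot fio2 inspired oxygen fraction in [0.21, 1].
#' @slot curves named list of \linkS4class{SensorCurve}, one per channel.
#' @export
setClass("ENoseMeasurement",
  representation(animalId = "character", group = "character",
                 timepoint = "character", fio2 = "numeric", curves = "list"))

setValidity("ENoseMeasurement", function(object) {
  msgs <- character()
  if (length(object@animalId) != 1L || !nzchar(object@animalId))
    msgs <- c(msgs, "animalId must be a single non-empty string")
  if (length(object@group) != 1L || !(object@group %in% GROUP_LEVELS))
    msgs <- c(msgs, sprintf("group must be one of: %s", paste(GROUP_LEVELS, collapse = ", ")))
  if (length(object@timepoint) != 1L || !nzchar(object@timepoint))
    msgs <- c(msgs, "timepoint must be a single non-empty string")
  if (length(object@fio2) != 1L || !is.finite(object@fio2) ||
      object@fio2 < 0.21 - 1e-12 || object@fio2 > 1)
    msgs <- c(msgs, "fio2 must be a single value in [0.21, 1]")
  if (length(object@curves) < 1L)
    msgs <- c(msgs, "at least one SensorCurve required")
  if (!all(vapply(object@curves, is, logical(1), "SensorCurve")))
    msgs <- c(msgs, "curves must all be SensorCurve objects")
  else {
    ids <- vapply(object@curves, function(x) x@channelId, character(1))
    if (anyDuplicated(ids))
      msgs <- c(msgs, "channel ids must be unique within a measurement")
    if (!is.null(names(object@curves)) && !identical(unname(names(object@curves)), unname(ids)))
      msgs <- c(msgs, "curve list names must match channel ids")
    ref <- object@curves[[1]]
    same <- vapply(object@curves, function(x)
      isTRUE(all.equal(x@times, ref@times)) &&
      isTRUE(all.equal(x@phaseBounds, ref@phaseBounds)), logical(1))
    if (!all(same))
      msgs <- c(msgs, "all curves must share times and phaseBounds")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ENoseMeasurement
#'
#' @param animalId subject identifier.
#' @param group \code{"control"}, \code{"LPS"} or \code{"calibration"}.
#' @param timepoint timepoint label.
#' @param fio2 inspired-oxygen fraction in [0.21, 1].
#' @param curves list of \linkS4class{SensorCurve} (names are set from
#'   channel ids).
#' @return A validated \linkS4class{ENoseMeasurement}.
#' @export
eNoseMeasurement <- function(animalId, group, timepoint, fio2, curves) {
  names(curves) <- vapply(curves, function(x) x@channelId, character(1))
  new("ENoseMeasurement", animalId = as.character(animalId),
      group = as.character(group), timepoint = as.character(timepoint),
      fio2 = as.numeric(fio2), curves = curves)
}

# ---- CalibrationSeries -----------------------------------------------------

#' CalibrationSeries: clean-air measurements across FiO2 levels
#'
#' Replicated clean-air e-Nose measurements taken at several inspired-oxygen
#' levels (default 21, 25, 30, 35, 40, 50 %, three replicates per level), the
#' raw material for building \linkS4class{CorrectionSurface} objects. The
#' reference level 0.21 must always be present.
#'
#' @slot levels strictly increasing FiO2 fractions containing 0.21.
#' @slot replicates list (one element per level, named by level) of lists of
#'   \linkS4class{ENoseMeasurement}.
#' @export
setClass("CalibrationSeries",
  representation(levels = "numeric", replicates = "list"))

setValidity("CalibrationSeries", function(object) {
  msgs <- character()
  lv <- object@levels
  if (length(lv) < 2L || any(diff(lv) <= 0))
    msgs <- c(msgs, "levels must be strictly increasing with length >= 2")
  if (!any(abs(lv - REFERENCE_FIO2) < 1e-9))
    msgs <- c(msgs, "reference level 0.21 must be present")
  if (length(object@replicates) != length(lv))
    msgs <- c(msgs, "one replicate list per level required")
  else for (i in seq_along(lv)) {
    reps <- object@replicates[[i]]
    if (length(reps) < 1L) { msgs <- c(msgs, "every level needs >= 1 replicate"); next }
    ok <- vapply(reps, function(m) is(m, "ENoseMeasurement") &&
                   abs(m@fio2 - lv[i]) < 1e-9, logical(1))
    if (!all(ok))
      msgs <- c(msgs, sprintf("replicates at level %.2f must be ENoseMeasurements carrying fio2 = %.2f", lv[i], lv[i]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CalibrationSeries
#'
#' @param levels FiO2 fractions (must contain 0.21, strictly increasing).
#' @param replicates list of lists of \linkS4class{ENoseMeasurement}, parallel
#'   to \code{levels}.
#' @return A validated \linkS4class{CalibrationSeries}.
#' @export
calibrationSeries <- function(levels, replicates) {
  names(replicates) <- formatC(levels, format = "g")
  new("CalibrationSeries", levels = as.numeric(levels), replicates = replicates)
}

# ---- CorrectionSurface -----------------------------------------------------

#' CorrectionSurface: bivariate FiO2 correction function k(t, FiO2)
#'
#' A per-channel correction surface built from a clean-air calibration series.
#' For the \code{"diff"} strategy k is the point-by-point difference between
#' the (baseline-removed) mean calibration curve at each level and the curve
#' at the 21 % reference; for \code{"ratio"} it is the point-by-point ratio.
#' Evaluation between grid nodes is bilinear; FiO2 values outside the
#' calibrated range are clamped to the nearest level with a warning.
#'
#' @slot channelId channel the surface corrects.
#' @slot strategy \code{"diff"} or \code{"ratio"}.
#' @slot gridTimes calibration time grid (seconds).
#' @slot gridLevels calibration FiO2 levels.
#' @slot kValues matrix time x level of correction values.
#' @slot referenceLevel the reference FiO2 (0.21).
#' @slot baselineMode \code{"matched"} (calibration curves baseline-removed
#'   with the strategy's own mode before differencing/ratioing) or
#'   \code{"raw"}.
#' @export
setClass("CorrectionSurface",
  representation(channelId = "character", strategy = "character",
                 gridTimes = "numeric", gridLevels = "numeric",
                 kValues = "matrix", referenceLevel = "numeric",
                 baselineMode = "character"))

setValidity("CorrectionSurface", function(object) {
  msgs <- character()
  if (!(object@strategy %in% c("diff", "ratio")))
    msgs <- c(msgs, "strategy must be 'diff' or 'ratio'")
  if (!identical(dim(object@kValues),
                 c(length(object@gridTimes), length(object@gridLevels))))
    msgs <- c(msgs, "kValues must be times x levels")
  iref <- which(abs(object@gridLevels - object@referenceLevel) < 1e-9)
  if (length(iref) != 1L)
    msgs <- c(msgs, "referenceLevel must be one of gridLevels")
  else {
    refcol <- object@kValues[, iref]
    want <- if (identical(object@strategy, "ratio")) 1 else 0
    if (any(abs(refcol - want) > 1e-12))
      msgs <- c(msgs, sprintf("reference-level column must be identically %g", want))
  }
  if (identical(object@strategy, "ratio") && any(object@kValues <= 0))
    msgs <- c(msgs, "ratio surfaces must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

# ---- FeatureTable ----------------------------------------------------------

#' FeatureTable: samples x (channel-feature) matrix with labels
#'
#' The interchange object between feature extraction and classification. Rows
#' are (animal, timepoint) samples; columns are channel x feature names such
#' as \code{TGS2610.amplitude}. A logical mask records cells removed by the
#' interquartile-range outlier screen (masked cells hold imputed values).
#'
#' @slot values numeric matrix, samples x features.
#' @slot sampleInfo data.frame with columns \code{animalId}, \code{group},
#'   \code{timepoint}, \code{fio2}, one row per sample.
#' @slot mask logical matrix, same shape as \code{values}; TRUE = screened out.
#' @export
setClass("FeatureTable",
  representation(values = "matrix", sampleInfo = "data.frame",
                 mask = "matrix"))

setValidity("FeatureTable", function(object) {
  msgs <- character()
  if (nrow(object@values) != nrow(object@sampleInfo))
    msgs <- c(msgs, "values and sampleInfo must have equal row counts")
  need <- c("animalId", "group", "timepoint", "fio2")
  if (!all(need %in% names(object@sampleInfo)))
    msgs <- c(msgs, "sampleInfo needs columns animalId, group, timepoint, fio2")
  if (!identical(dim(object@mask), dim(object@values)))
    msgs <- c(msgs, "mask must match values in shape")
  if (anyDuplicated(rownames(object@values)))
    msgs <- c(msgs, "sample keys (rownames) must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric samples x features matrix with rownames
#'   \code{"<animal>.<timepoint>"} and feature column names.
#' @param sampleInfo data.frame with \code{animalId}, \code{group},
#'   \code{timepoint}, \code{fio2}.
#' @param mask optional logical matrix of screened cells (default none).
#' @return A validated \linkS4class{FeatureTable}.
#' @export
featureTable <- function(values, sampleInfo, mask = NULL) {
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values),
                   dimnames = dimnames(values))
  }
  new("FeatureTable", values = values, sampleInfo = sampleInfo, mask = mask)
}

# ---- PressureTrace ---------------------------------------------------------

#' PressureTrace: ventilator expiratory-line pressure signal
#'
#' @slot times seconds, uniform strictly increasing grid.
#' @slot pressure pressure in cmH2O.
#' @slot threshold exhalation-detection threshold in cmH2O.
#' @export
setClass("PressureTrace",
  representation(times = "numeric", pressure = "numeric",
                 threshold = "numeric"))

setValidity("PressureTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@pressure))
    msgs <- c(msgs, "times and pressure must have equal length")
  g <- .checkUniformGrid(object@times)
  if (!is.null(g)) msgs <- c(msgs, g)
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msgs <- c(msgs, "threshold must be a single finite value")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PressureTrace
#'
#' @param times seconds (uniform grid).
#' @param pressure cmH2O.
#' @param threshold detection threshold in cmH2O.
#' @return A validated \linkS4class{PressureTrace}.
#' @export
pressureTrace <- function(times, pressure, threshold) {
  new("PressureTrace", times = as.numeric(times),
      pressure = as.numeric(pressure), threshold = as.numeric(threshold))
}

# ---- SensorModel -----------------------------------------------------------

#' SensorModel: forward model of one MOS channel
#'
#' Minimal first-order response model of an n-type MOS sensor: exposure to
#' reducing breath volatiles lowers resistance (factor \code{1 - alphaVc *
#' vcLoad * g(t)}), oxygen above room air raises it (term \code{betaO2 *
#' (fio2 - 0.21) * g(t)}), with \code{g(t)} a first-order on/off envelope
#' (time constants \code{tauOn}, \code{tauOff}) that is zero in the "before"
#' phase, charges during "during" and decays in "after". The oxygen term is
#' combined additively or multiplicatively according to \code{o2Mode}.
#' Multiplicative lognormal noise with coefficient of variation \code{noiseCv}.
#'
#' @slot channelId channel identifier.
#' @slot r0 baseline resistance in ohms (> 0).
#' @slot betaO2 fractional resistance increase per unit FiO2 above 0.21.
#' @slot alphaVc maximal fractional resistance decrease at unit VC load, in [0, 1).
#' @slot tauOn response time constant, seconds.
#' @slot tauOff recovery time constant, seconds.
#' @slot noiseCv multiplicative noise coefficient of variation.
#' @slot o2Mode \code{"additive"} or \code{"multiplicative"}.
#' @export
setClass("SensorModel",
  representation(channelId = "character", r0 = "numeric", betaO2 = "numeric",
                 alphaVc = "numeric", tauOn = "numeric", tauOff = "numeric",
                 noiseCv = "numeric", o2Mode = "character"))

setValidity("SensorModel", function(object) {
  msgs <- character()
  if (object@r0 <= 0) msgs <- c(msgs, "r0 must be > 0")
  if (object@alphaVc < 0 || object@alphaVc >= 1)
    msgs <- c(msgs, "alphaVc must lie in [0, 1)")
  if (object@tauOn <= 0 || object@tauOff <= 0)
    msgs <- c(msgs, "tauOn and tauOff must be > 0")
  if (object@noiseCv < 0) msgs <- c(msgs, "noiseCv must be >= 0")
  if (!(object@o2Mode %in% c("additive", "multiplicative")))
    msgs <- c(msgs, "o2Mode must be 'additive' or 'multiplicative'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SensorModel
#'
#' @param channelId channel identifier.
#' @param r0 baseline resistance, ohms.
#' @param betaO2 oxygen sensitivity (fractional increase per unit FiO2 above 0.21).
#' @param alphaVc VC sensitivity (maximal fractional decrease at unit load).
#' @param tauOn,tauOff response / recovery time constants, seconds.
#' @param noiseCv multiplicative noise CV (default 0.01).
#' @param o2Mode \code{"multiplicative"} (default) or \code{"additive"}.
#' @return A validated \linkS4class{SensorModel}.
#' @export
sensorModel <- function(channelId, r0, betaO2, alphaVc, tauOn, tauOff,
                        noiseCv = 0.01, o2Mode = "multiplicative") {
  new("SensorModel", channelId = as.character(channelId), r0 = r0,
      betaO2 = betaO2, alphaVc = alphaVc, tauOn = tauOn, tauOff = tauOff,
      noiseCv = noiseCv, o2Mode = o2Mode)
}

# ---- CohortSpec ------------------------------------------------------------

#' CohortSpec: design of a synthetic study cohort
#'
#' Describes the animals, timepoints, group-dependent volatile-compound (VC)
#' load schedule, FiO2 escalation policy and physiological trends that
#' \code{\link{simulateCohort}} realises. The default spec emulates the study
#' design: 9 control / 10 LPS animals over 8 timepoints, a VC separation
#' growing with time since LPS administration, FiO2 flat near 0.30 in
#' controls and escalating after t30 in the LPS group, MAP kept above
#' 80 mmHg in controls and falling to 40--60 mmHg under LPS.
#'
#' @slot nControl,nLps animal counts (>= 1).
#' @slot timepoints ordered timepoint labels.
#' @slot vcEffect matrix timepoints x c(control, LPS): mean VC load per group.
#' @slot vcSd between-sample SD of the VC load draw.
#' @slot fio2Policy matrix timepoints x c(control, LPS): assigned FiO2.
#' @slot physioParams list of physiological trend parameters (see
#'   \code{\link{defaultPhysioParams}}).
#' @slot seed integer seed driving all randomness of the cohort.
#' @export
setClass("CohortSpec",
  representation(nControl = "numeric", nLps = "numeric",
                 timepoints = "character", vcEffect = "matrix",
                 vcSd = "numeric", fio2Policy = "matrix",
                 physioParams = "list", seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nControl < 1 || object@nLps < 1)
    msgs <- c(msgs, "animal counts must be >= 1")
  tp <- object@timepoints
  for (m in c("vcEffect", "fio2Policy")) {
    mm <- slot(object, m)
    if (!identical(rownames(mm), tp) ||
        !identical(colnames(mm), c("control", "LPS")))
      msgs <- c(msgs, sprintf("%s must have rownames = timepoints and colnames = c('control','LPS')", m))
  }
  if (any(object@fio2Policy < 0.21 - 1e-9 | object@fio2Policy > 1))
    msgs <- c(msgs, "fio2Policy values must lie in [0.21, 1]")
  if (object@vcSd < 0) msgs <- c(msgs, "vcSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})
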