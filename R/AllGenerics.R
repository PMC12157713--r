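# Accessor generics. Slot access from user code should go through these.

#' @rdname accessors
#' @param object an object of a septanose class.
#' @export
setGeneric("channelId", function(object) standardGeneric("channelId"))
#' @rdname accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("resistance", function(object) standardGeneric("resistance"))
#' @rdname accessors
#' @export
setGeneric("phaseBounds", function(object) standardGeneric("phaseBounds"))
#' @rdname accessors
#' @export
setGeneric("animalId", function(object) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("timepointLabel", function(object) standardGeneric("timepointLabel"))
#' @rdname accessors
#' @export
setGeneric("fio2", function(object) standardGeneric("fio2"))
#' @rdname accessors
#' @export
setGeneric("sensorCurves", function(object) standardGeneric("sensorCurves"))
#' @rdname accessors
#' @export
setGeneric("calibrationLevels", function(object) standardGeneric("calibrationLevels"))
#' @rdname accessors
#' @param level calibration FiO2 level.
#' @export
setGeneric("calibrationReplicates", function(object, level) standardGeneric("calibrationReplicates"))
#' @rdname accessors
#' @export
setGeneric("surfaceStrategy", function(object) standardGeneric("surfaceStrategy"))
#' @rdname accessors
#' @export
setGeneric("kValues", function(object) standardGeneric("kValues"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureMask", function(object) standardGeneric("featureMask"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' Accessors for septanose classes
#'
#' Read-only accessors for the slots of \linkS4class{SensorCurve},
#' \linkS4class{ENoseMeasurement}, \linkS4class{CalibrationSeries},
#' \linkS4class{CorrectionSurface} and \linkS4class{FeatureTable}.
#'
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("channelId", "SensorCurve", function(object) object@channelId)
#' @rdname accessors
setMethod("curveTimes", "SensorCurve", function(object) object@times)
#' @rdname accessors
setMethod("resistance", "SensorCurve", function(object) object@resistance)
#' @rdname accessors
setMethod("phaseBounds", "SensorCurve", function(object) object@phaseBounds)

#' @rdname accessors
setMethod("animalId", "ENoseMeasurement", function(object) object@animalId)
#' @rdname accessors
setMethod("groupLabel", "ENoseMeasurement", function(object) object@group)
#' @rdname accessors
setMethod("timepointLabel", "ENoseMeasurement", function(object) object@timepoint)
#' @rdname accessors
setMethod("fio2", "ENoseMeasurement", function(object) object@fio2)
#' @rdname accessors
setMethod("sensorCurves", "ENoseMeasurement", function(object) object@curves)

#' @rdname accessors
setMethod("calibrationLevels", "CalibrationSeries", function(object) object@levels)
#' @rdname accessors
setMethod("calibrationReplicates", "CalibrationSeries", function(object, level) {
  i <- which(abs(object@levels - level) < 1e-9)
  if (length(i) != 1L) stop("level ", level, " not present in calibration series")
  object@replicates[[i]]
})

#' @rdname accessors
setMethod("channelId", "CorrectionSurface", function(object) object@channelId)
#' @rdname accessors
setMethod("surfaceStrategy", "CorrectionSurface", function(object) object@strategy)
#' @rdname accessors
setMethod("kValues", "CorrectionSurface", function(object) object@kValues)
#' @rdname accessors
setMethod("calibrationLevels", "CorrectionSurface", function(object) object@gridLevels)
#' @rdname accessors
setMethod("curveTimes", "CorrectionSurface", function(object) object@gridTimes)

#' @rdname accessors
setMethod("featureValues", "FeatureTable", function(object) object@values)
#' @rdname accessors
setMethod("featureMask", "FeatureTable", function(object) object@mask)
#' @rdname accessors
setMethod("sampleInfo", "FeatureTable", function(object) object@sampleInfo)

#' @rdname accessors
setMethod("channelId", "SensorModel", function(object) object@channelId)

setMethod("show", "SensorCurve", function(object) {
  cat(sprintf("SensorCurve '%s': %d samples, %.0f-%.0f s, phases at %s s\n",
              object@channelId, length(object@times), min(object@times),
              max(object@times), paste(object@phaseBounds, collapse = "/")))
  cat(sprintf("  resistance: %.4g .. %.4g ohm\n",
              min(object@resistance), max(object@resistance)))
})

setMethod("show", "ENoseMeasurement", function(object) {
  cat(sprintf("ENoseMeasurement: animal %s (%s), %s, FiO2 %.2f\n",
              object@animalId, object@group, object@timepoint, object@fio2))
  cat(sprintf("  %d channels x %d samples: %s\n", length(object@curves),
              length(object@curves[[1]]@times),
              paste(names(object@curves), collapse = ", ")))
})

setMethod("show", "CalibrationSeries", function(object) {
  cat(sprintf("CalibrationSeries: FiO2 levels %s\n",
              paste(sprintf("%.0f%%", 100 * object@levels), collapse = ", ")))
  cat(sprintf("  replicates per level: %s\n",
              paste(vapply(object@replicates, length, integer(1)), collapse = ", ")))
})

setMethod("show", "CorrectionSurface", function(object) {
  cat(sprintf("CorrectionSurface '%s' (k_%s, %s calibration baseline)\n",
              object@channelId, object@strategy, object@baselineMode))
  cat(sprintf("  grid: %d time points x %d FiO2 levels (%.0f%%..%.0f%%), reference %.0f%%\n",
              length(object@gridTimes), length(object@gridLevels),
              100 * min(object@gridLevels), 100 * max(object@gridLevels),
              100 * object@referenceLevel))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features, %d masked cells\n",
              nrow(object@values), ncol(object@values), sum(object@mask)))
  tb <- table(object@sampleInfo$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

setMethod("show", "SensorModel", function(object) {
  cat(sprintf("SensorModel '%s': r0=%.3g ohm, betaO2=%.2f, alphaVc=%.2f, tau=%g/%g s, CV=%.3g, O2 %s\n",
              object@channelId, object@r0, object@betaO2, object@alphaVc,
              object@tauOn, object@tauOff, object@noiseCv, object@o2Mode))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d control + %d LPS animals, %d timepoints (%s..%s), seed %d\n",
              object@nControl, object@nLps, length(object@timepoints),
              object@timepoints[1], object@timepoints[length(object@timepoints)],
              as.integer(object@seed)))
})
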