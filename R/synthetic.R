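# Synthetic-data generator: sensor forward model, clean-air calibration
# series, and full study cohorts (e-Nose measurements + physiology).
#
# The forward model is the minimal first-order model consistent with n-type
# MOS directionality: breath volatiles (VC load) depress resistance, oxygen
# above room air raises it. The additive O2 mode pairs exactly with the
# subtractive (k_diff) correction, the multiplicative mode with k_ratio:
#   additive:        R(t) = r0 (1 - a v g(t)) + r0 b (f - 0.21) g(t)
#   multiplicative:  R(t) = r0 (1 - a v g(t)) (1 + b (f - 0.21) g(t))
# with g(t) = 0 in "before", 1 - exp(-(t - t_on)/tauOn) in "during", and
# first-order decay with tauOff in "after".

.envelope <- function(times, phaseBounds, tauOn, tauOff) {
  b1 <- phaseBounds[1]; b2 <- phaseBounds[2]
  g <- numeric(length(times))
  dur <- times >= b1 & times < b2
  aft <- times >= b2
  g[dur] <- 1 - exp(-(times[dur] - b1) / tauOn)
  gEnd <- 1 - exp(-(b2 - b1) / tauOn)
  g[aft] <- gEnd * exp(-(times[aft] - b2) / tauOff)
  g
}

.curveNoiseless <- function(s, vcLoad, fio2, times, phaseBounds) {
  g <- .envelope(times, phaseBounds, s@tauOn, s@tauOff)
  vc <- 1 - s@alphaVc * vcLoad * g
  o2 <- s@betaO2 * (fio2 - REFERENCE_FIO2) * g
  if (identical(s@o2Mode, "additive")) s@r0 * vc + s@r0 * o2
  else s@r0 * vc * (1 + o2)
}

#' Simulate one sensor response curve
#'
#' Forward-simulates a \linkS4class{SensorModel} exposed to a sample with a
#' given volatile-compound load and oxygen fraction over the three-phase
#' protocol. The "before" phase sits at the oxygen-free baseline (reference
#' air), the "during" phase relaxes toward the combined VC/O2 level with time
#' constant \code{tauOn}, the "after" phase recovers with \code{tauOff}.
#' Noise is multiplicative lognormal with the model's CV and unit mean.
#'
#' @param s a \linkS4class{SensorModel}.
#' @param vcLoad dimensionless VC load (>= 0; 0 = clean air).
#' @param fio2 oxygen fraction of the sample, in [0.21, 1].
#' @param phaseBounds phase boundaries, seconds.
#' @param rateHz sampling rate (default 1 Hz).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return A \linkS4class{SensorCurve}.
#' @export
simulateCurve <- function(s, vcLoad, fio2, phaseBounds = c(60, 360, 960),
                          rateHz = 1, seed = NULL) {
  validObject(s)
  if (vcLoad < 0) stop("vcLoad must be >= 0")
  if (s@alphaVc * vcLoad >= 1)
    stop("vcLoad too large: resistance would reach zero (alphaVc * vcLoad >= 1)")
  times <- seq(0, phaseBounds[3], by = 1 / rateHz)
  r <- .curveNoiseless(s, vcLoad, fio2, times, phaseBounds)
  if (s@noiseCv > 0) {
    sdlog <- sqrt(log(1 + s@noiseCv^2))
    draw <- function() exp(stats::rnorm(length(times), -sdlog^2 / 2, sdlog))
    fac <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
    r <- r * fac
  }
  sensorCurve(s@channelId, times, r, phaseBounds)
}

#' Default sensor models for the eight-channel array
#'
#' One \linkS4class{SensorModel} per physical channel with hand-set, channel-
#' varied parameters (baseline resistances of a few tens of kilo-ohm, oxygen
#' sensitivities and response kinetics in the range typical of Figaro TGS
#' devices). These are documented modelling assumptions, not estimates from
#' any measured sensor.
#'
#' @param noiseCv noise CV applied to every channel (default 0.01).
#' @param o2Mode O2 combination mode for every channel (default multiplicative).
#' @return Named list of \linkS4class{SensorModel}, one per channel.
#' @export
defaultSensorModels <- function(noiseCv = 0.01, o2Mode = "multiplicative") {
  p <- data.frame(
    channelId = defaultChannelIds(),
    r0      = c(42e3, 45e3, 28e3, 26e3, 18e3, 35e3, 22e3, 55e3),
    betaO2  = c(1.00, 0.95, 0.70, 0.75, 0.55, 0.80, 0.60, 1.10),
    alphaVc = c(0.55, 0.52, 0.40, 0.42, 0.30, 0.45, 0.35, 0.60),
    tauOn   = c(30, 32, 25, 27, 20, 28, 22, 35),
    tauOff  = c(90, 95, 75, 80, 60, 85, 70, 100))
  models <- lapply(seq_len(nrow(p)), function(i)
    sensorModel(p$channelId[i], p$r0[i], p$betaO2[i], p$alphaVc[i],
                p$tauOn[i], p$tauOff[i], noiseCv = noiseCv, o2Mode = o2Mode))
  stats::setNames(models, p$channelId)
}

.cleanAirMeasurement <- function(models, fio2, label, phaseBounds, rateHz) {
  curves <- lapply(models, simulateCurve, vcLoad = 0, fio2 = fio2,
                   phaseBounds = phaseBounds, rateHz = rateHz, seed = NULL)
  eNoseMeasurement(label, "calibration", label, fio2, curves)
}

#' Simulate a clean-air calibration series
#'
#' Clean air (zero VC load) from a test lung at each FiO2 level, replicated;
#' replicate-to-replicate variation comes from sensor noise only. Default:
#' levels 21, 25, 30, 35, 40, 50 % with three replicates each (18
#' measurements).
#'
#' @param models named list of \linkS4class{SensorModel} (one per channel).
#' @param levels FiO2 fractions; must include the 0.21 reference.
#' @param nReplicates replicates per level (default 3).
#' @param seed integer seed.
#' @param phaseBounds,rateHz protocol grid passed to \code{\link{simulateCurve}}.
#' @return A \linkS4class{CalibrationSeries}.
#' @export
simulateCalibrationSeries <- function(models, levels = c(0.21, 0.25, 0.30, 0.35, 0.40, 0.50),
                                      nReplicates = 3, seed = 20,
                                      phaseBounds = c(60, 360, 960), rateHz = 1) {
  if (!any(abs(levels - REFERENCE_FIO2) < 1e-9))
    stop("calibration levels must include the 0.21 reference")
  levels <- sort(levels)
  reps <- withr::with_seed(as.integer(seed), {
    lapply(levels, function(lv)
      lapply(seq_len(nReplicates), function(j)
        .cleanAirMeasurement(models, lv, sprintf("cal_%03.0f_r%d", 1000 * lv, j),
                             phaseBounds, rateHz)))
  })
  calibrationSeries(levels, reps)
}

# ---- cohort specification --------------------------------------------------

.tpMatrix <- function(timepoints, control, lps) {
  matrix(c(control, lps), ncol = 2,
         dimnames = list(timepoints, c("control", "LPS")))
}

#' Default group-wise VC-load schedule
#'
#' Mean VC load per group and timepoint. Controls sit at a constant low load;
#' the LPS group's load grows monotonically with time since administration,
#' mirroring the escalating endotoxin dose. Magnitudes are modelling
#' assumptions (the source data quantify no effect sizes).
#'
#' @param timepoints timepoint labels.
#' @param lpsMax LPS-group load at the last timepoint (default 1).
#' @param controlLoad constant control load (default 0.1).
#' @return Matrix timepoints x c(control, LPS).
#' @export
defaultVcEffect <- function(timepoints = STUDY_TIMEPOINTS, lpsMax = 1,
                            controlLoad = 0.1) {
  minutes <- as.numeric(sub("^t", "", timepoints))
  ramp <- controlLoad + (lpsMax - controlLoad) * pmin(1, minutes / 180)
  .tpMatrix(timepoints, rep(controlLoad, length(timepoints)), ramp)
}

#' Default FiO2 assignment policy
#'
#' Controls stay near 0.30 throughout; the LPS group's FiO2 escalates after
#' t30 as oxygenation deteriorates, up to 0.50 (the top of the calibration
#' hull) at t180. This is the group-correlated confounding channel.
#'
#' @param timepoints timepoint labels.
#' @return Matrix timepoints x c(control, LPS) of FiO2 fractions.
#' @export
defaultFio2Policy <- function(timepoints = STUDY_TIMEPOINTS) {
  ctrl <- rep(0.30, length(timepoints))
  lps <- c(0.30, 0.30, 0.30, 0.35, 0.40, 0.45, 0.48, 0.50)[seq_along(timepoints)]
  .tpMatrix(timepoints, ctrl, lps)
}

#' Default physiological trend parameters
#'
#' Group-wise means over time and SDs for MAP, HR and temperature, plus
#' pulse-pressure offsets used to derive DBP/SBP around MAP and fixed PEEP /
#' PIP settings. Control MAP is held above 80 mmHg; LPS MAP declines toward
#' the 40--60 mmHg band, HR and temperature rise.
#'
#' @param timepoints timepoint labels.
#' @return Named list of parameter matrices/scalars.
#' @export
defaultPhysioParams <- function(timepoints = STUDY_TIMEPOINTS) {
  k <- length(timepoints)
  minutes <- as.numeric(sub("^t", "", timepoints))
  frac <- pmin(1, minutes / 180)
  list(
    mapMean = .tpMatrix(timepoints, rep(88, k), 88 - 38 * frac),
    mapSd = 4,
    hrMean = .tpMatrix(timepoints, rep(92, k), 92 + 48 * frac),
    hrSd = 6,
    tempMean = .tpMatrix(timepoints, rep(38.4, k), 38.4 + 2.0 * frac),
    tempSd = 0.25,
    pulseDown = 14, pulseDownSd = 2,   # MAP - DBP
    pulseUp = 24, pulseUpSd = 3,       # SBP - MAP
    peep = 5, pip = 22)
}

#' Construct a CohortSpec
#'
#' @param nControl,nLps animal counts (study defaults 9 and 10).
#' @param timepoints ordered timepoint labels.
#' @param vcEffect VC-load schedule matrix (\code{\link{defaultVcEffect}}).
#' @param vcSd SD of the per-measurement VC-load draw (default 0.05).
#' @param fio2Policy FiO2 matrix (\code{\link{defaultFio2Policy}}).
#' @param physioParams physiology parameters (\code{\link{defaultPhysioParams}}).
#' @param seed integer seed.
#' @return A validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nControl = 9, nLps = 10, timepoints = STUDY_TIMEPOINTS,
                       vcEffect = defaultVcEffect(timepoints), vcSd = 0.05,
                       fio2Policy = defaultFio2Policy(timepoints),
                       physioParams = defaultPhysioParams(timepoints),
                       seed = 1) {
  new("CohortSpec", nControl = nControl, nLps = nLps, timepoints = timepoints,
      vcEffect = vcEffect, vcSd = vcSd, fio2Policy = fio2Policy,
      physioParams = physioParams, seed = seed)
}

#' Scenario cohort specs
#'
#' Convenience constructors for the three benchmark scenarios exercised by
#' the test harness:
#' \describe{
#'   \item{nullCohortSpec}{zero VC effect in both groups, shared flat FiO2,
#'     identical physiology — group labels carry no signal at all.}
#'   \item{strongEffectCohortSpec}{the default VC schedule (LPS separation
#'     many noise SDs by t90) with a flat shared FiO2, isolating the
#'     volatile-compound signal.}
#'   \item{confoundedCohortSpec}{zero VC effect but the default group-coupled
#'     FiO2 escalation — any e-Nose classification signal is pure oxygen
#'     confounding.}
#' }
#'
#' @param seed integer seed.
#' @param nControl,nLps animal counts (default 10 + 10 for null, study sizes
#'   otherwise).
#' @return A \linkS4class{CohortSpec}.
#' @export
nullCohortSpec <- function(seed = 1, nControl = 10, nLps = 10) {
  tp <- STUDY_TIMEPOINTS
  pp <- defaultPhysioParams(tp)
  for (m in c("mapMean", "hrMean", "tempMean")) pp[[m]][, "LPS"] <- pp[[m]][, "control"]
  cohortSpec(nControl, nLps, tp,
             vcEffect = .tpMatrix(tp, rep(0.1, 8), rep(0.1, 8)),
             fio2Policy = .tpMatrix(tp, rep(0.30, 8), rep(0.30, 8)),
             physioParams = pp, seed = seed)
}

#' @rdname nullCohortSpec
#' @export
strongEffectCohortSpec <- function(seed = 1, nControl = 9, nLps = 10) {
  tp <- STUDY_TIMEPOINTS
  minutes <- as.numeric(sub("^t", "", tp))
  # rapid-onset schedule: >= 5 noise-SD VC separation at every post-baseline
  # timepoint (6 SD at t5, full separation from t15 on)
  ramp <- 0.1 + 0.9 * pmin(1, minutes / 15)
  cohortSpec(nControl, nLps, tp,
             vcEffect = .tpMatrix(tp, rep(0.1, 8), ramp),
             fio2Policy = .tpMatrix(tp, rep(0.30, 8), rep(0.30, 8)),
             seed = seed)
}

#' @rdname nullCohortSpec
#' @export
confoundedCohortSpec <- function(seed = 1, nControl = 9, nLps = 10) {
  tp <- STUDY_TIMEPOINTS
  cohortSpec(nControl, nLps, tp,
             vcEffect = .tpMatrix(tp, rep(0.1, 8), rep(0.1, 8)),
             seed = seed)
}

# ---- cohort realisation ----------------------------------------------------

.simulatePhysioRecord <- function(pp, tp, group, animal, fio2) {
  map <- stats::rnorm(1, pp$mapMean[tp, group], pp$mapSd)
  down <- abs(stats::rnorm(1, pp$pulseDown, pp$pulseDownSd))
  up <- abs(stats::rnorm(1, pp$pulseUp, pp$pulseUpSd))
  map <- max(map, down + 5)  # keep DBP positive
  data.frame(animalId = animal, group = group, timepoint = tp,
             MAP = map, DBP = map - down, SBP = map + up,
             HR = max(30, stats::rnorm(1, pp$hrMean[tp, group], pp$hrSd)),
             T = stats::rnorm(1, pp$tempMean[tp, group], pp$tempSd),
             fio2 = fio2, peep = pp$peep, pip = pp$pip)
}

#' Simulate a full study cohort
#'
#' Realises a \linkS4class{CohortSpec}: one e-Nose measurement and one
#' physiological record per animal per timepoint. VC loads are drawn
#' independently per measurement around the group schedule; FiO2 follows the
#' policy and is recorded in both the measurement and the physiological
#' record (the confounding channel). Physiology satisfies DBP <= MAP <= SBP.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param models named list of \linkS4class{SensorModel}.
#' @param phaseBounds,rateHz protocol grid.
#' @return list with \code{measurements} (list of
#'   \linkS4class{ENoseMeasurement}) and \code{physio} (data.frame of
#'   per-timepoint records).
#' @export
simulateCohort <- function(spec, models = defaultSensorModels(),
                           phaseBounds = c(60, 360, 960), rateHz = 1) {
  validObject(spec)
  animals <- data.frame(
    animalId = c(sprintf("C%02d", seq_len(spec@nControl)),
                 sprintf("L%02d", seq_len(spec@nLps))),
    group = rep(c("control", "LPS"), c(spec@nControl, spec@nLps)))
  withr::with_seed(as.integer(spec@seed), {
    measurements <- list()
    physio <- list()
    for (i in seq_len(nrow(animals))) {
      an <- animals$animalId[i]; gr <- animals$group[i]
      for (tp in spec@timepoints) {
        vc <- max(0, stats::rnorm(1, spec@vcEffect[tp, gr], spec@vcSd))
        f <- spec@fio2Policy[tp, gr]
        curves <- lapply(models, simulateCurve, vcLoad = vc, fio2 = f,
                         phaseBounds = phaseBounds, rateHz = rateHz, seed = NULL)
        measurements[[length(measurements) + 1L]] <-
          eNoseMeasurement(an, gr, tp, f, curves)
        physio[[length(physio) + 1L]] <-
          .simulatePhysioRecord(spec@physioParams, tp, gr, an, f)
      }
    }
    list(measurements = measurements, physio = do.call(rbind, physio))
  })
}
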