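# Small in-code fixtures: two-channel sensor array with short phases so unit
# tests run in milliseconds. Full-size (8-channel, 960 s) objects are built
# only where a test needs them.

TINY_BOUNDS <- c(10, 60, 120)  # 10 s before, 50 s during, 60 s after

tinyModels <- function(noiseCv = 0, o2Mode = "multiplicative") {
  list(
    chA = sensorModel("chA", r0 = 1e4, betaO2 = 0.8, alphaVc = 0.5,
                      tauOn = 5, tauOff = 12, noiseCv = noiseCv, o2Mode = o2Mode),
    chB = sensorModel("chB", r0 = 2.4e4, betaO2 = 0.6, alphaVc = 0.4,
                      tauOn = 6, tauOff = 15, noiseCv = noiseCv, o2Mode = o2Mode))
}

tinyCalibration <- function(models = tinyModels(), seed = 7, nReplicates = 3) {
  simulateCalibrationSeries(models, nReplicates = nReplicates, seed = seed,
                            phaseBounds = TINY_BOUNDS, rateHz = 1)
}

tinyMeasurement <- function(models = tinyModels(), vcLoad = 1, fio2 = 0.30,
                            animal = "A1", group = "LPS", timepoint = "t60",
                            seed = 5) {
  curves <- withr::with_seed(seed, lapply(models, simulateCurve,
    vcLoad = vcLoad, fio2 = fio2, phaseBounds = TINY_BOUNDS, rateHz = 1))
  eNoseMeasurement(animal, group, timepoint, fio2, curves)
}

# constant-resistance measurement (hand-built curves)
constMeasurement <- function(value, channels = c("chA", "chB"), fio2 = 0.21,
                             label = "cal", n = 121, bounds = TINY_BOUNDS) {
  t <- seq(0, bounds[3], length.out = n)
  curves <- lapply(channels, function(ch)
    sensorCurve(ch, t, rep(value, n), bounds))
  eNoseMeasurement(label, "calibration", label, fio2, curves)
}

# small deterministic classification table: two Gaussian blobs per group,
# separated by `sep` on the first feature with within-group SD `noiseSd`
# (z-scoring bounds the standardized separation of a bimodal feature near 2,
# so "clearly separable" means small noiseSd, not large sep)
blobTable <- function(nPerGroup = 6, timepoints = c("t5", "t30"), sep = 8,
                      nFeat = 4, seed = 42, noiseSd = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in c("control", "LPS")) {
      for (i in seq_len(nPerGroup)) {
        an <- sprintf("%s%02d", ifelse(g == "control", "C", "L"), i)
        for (tp in timepoints) {
          x <- stats::rnorm(nFeat, 0, noiseSd)
          if (g == "LPS") x <- x + sep
          rows[[length(rows) + 1L]] <- data.frame(
            animalId = an, group = g, timepoint = tp, fio2 = 0.3,
            t(stats::setNames(x, paste0("f", seq_len(nFeat)))))
        }
      }
    }
    do.call(rbind, rows)
  })
}
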