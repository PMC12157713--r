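test_that("mean level curve is the pointwise arithmetic mean of replicates", {
  reps <- lapply(c(10e3, 12e3, 14e3), constMeasurement)
  cs <- calibrationSeries(c(0.21, 0.30),
                          list(reps, lapply(reps, function(m) {
                            m@fio2 <- 0.30
                            m
                          })))
  m <- meanLevelCurve(cs, "chA", 0.21)
  expect_equal(resistance(m), rep(12e3, 121))
  # single replicate passes through unchanged
  cs1 <- calibrationSeries(c(0.21, 0.30), list(reps[1], list({
    x <- reps[[2]]; x@fio2 <- 0.30; x
  })))
  expect_equal(resistance(meanLevelCurve(cs1, "chA", 0.21)), rep(10e3, 121))
})

test_that("baseline removal pins the first sample to 0 or 1", {
  t <- 0:10
  c1 <- sensorCurve("chA", t, c(10, 8, 6, rep(6, 8)) * 1e3, c(1, 8, 10))
  sub <- removeBaseline(c1, "subtract")
  expect_equal(resistance(sub)[1:3], c(0, -2e3, -4e3), ignore_attr = TRUE)
  div <- removeBaseline(c1, "divide")
  expect_equal(resistance(div)[1], 1, ignore_attr = TRUE)
  const <- sensorCurve("chA", t, rep(5e3, 11), c(1, 8, 10))
  expect_equal(resistance(removeBaseline(const, "subtract")),
               rep(0, 11), ignore_attr = TRUE)
  expect_equal(resistance(removeBaseline(const, "divide")),
               rep(1, 11), ignore_attr = TRUE)
})

test_that("degenerate calibration (no oxygen sensitivity) gives trivial surfaces", {
  models <- lapply(tinyModels(noiseCv = 0), function(m) {
    m@betaO2 <- 0
    m
  })
  cs <- tinyCalibration(models)
  kd <- buildSurface(cs, "chA", "diff")
  kr <- buildSurface(cs, "chA", "ratio")
  expect_true(all(kValues(kd) == 0))
  expect_true(all(kValues(kr) == 1))
})

test_that("surfaces honor the reference identity at every grid node", {
  cs <- tinyCalibration(tinyModels(noiseCv = 0.02))
  for (strat in c("diff", "ratio")) {
    k <- buildSurface(cs, "chB", strat)
    want <- if (strat == "ratio") 1 else 0
    expect_equal(evaluateSurface(k, curveTimes(k), 0.21),
                 rep(want, length(curveTimes(k))))
  }
})

test_that("additive calibration reproduces the closed-form k_diff plateau", {
  models <- tinyModels(noiseCv = 0, o2Mode = "additive")
  cs <- tinyCalibration(models)
  k <- buildSurface(cs, "chA", "diff")
  tEnd <- TINY_BOUNDS[2] - 1                      # end of during phase
  gEnd <- 1 - exp(-(tEnd - TINY_BOUNDS[1]) / 5)
  for (f in c(0.25, 0.40, 0.50))
    expect_equal(evaluateSurface(k, tEnd, f), 1e4 * 0.8 * (f - 0.21) * gEnd,
                 tolerance = 1e-10)
})

test_that("surface evaluation is bilinear, clamps FiO2, and rejects bad times", {
  cs <- tinyCalibration(tinyModels(noiseCv = 0, o2Mode = "additive"))
  k <- buildSurface(cs, "chA", "diff")
  # node exactness
  expect_equal(evaluateSurface(k, 30, 0.40), kValues(k)[31, 5])
  # midway between levels = mean of node values (generator linear in level)
  mid <- evaluateSurface(k, 30, 0.275)
  expect_equal(mid, (kValues(k)[31, 2] + kValues(k)[31, 3]) / 2)
  expect_warning(v <- evaluateSurface(k, 30, 0.60), "clamped")
  expect_equal(v, kValues(k)[31, 6])
  expect_error(evaluateSurface(k, 500, 0.30), "outside the calibration grid")
})

test_that("correction at the reference FiO2 is the identity map", {
  models <- tinyModels(noiseCv = 0)
  cs <- tinyCalibration(models)
  samp <- sensorCurves(tinyMeasurement(models, vcLoad = 0.8, fio2 = 0.21))[["chA"]]
  for (strat in c("diff", "ratio")) {
    mode <- if (strat == "diff") "subtract" else "divide"
    k <- buildSurface(cs, "chA", strat)
    b <- removeBaseline(samp, mode)
    corr <- applyCorrection(b, k, 0.21)
    expect_equal(resistance(corr), resistance(b))
  }
})

test_that("noise-free collapse is exact for matched generator/strategy pairs", {
  for (cfg in list(list(mode = "additive", strat = "diff", bmode = "subtract"),
                   list(mode = "multiplicative", strat = "ratio", bmode = "divide"))) {
    models <- tinyModels(noiseCv = 0, o2Mode = cfg$mode)
    cs <- tinyCalibration(models)
    k <- buildSurface(cs, "chA", cfg$strat)
    ref <- removeBaseline(simulateCurve(models$chA, 1, 0.21, TINY_BOUNDS, 1),
                          cfg$bmode)
    for (f in calibrationLevels(cs)) {
      samp <- removeBaseline(simulateCurve(models$chA, 1, f, TINY_BOUNDS, 1),
                             cfg$bmode)
      corr <- applyCorrection(samp, k, f)
      expect_lt(max(abs(resistance(corr) - resistance(ref))),
                1e-9 * models$chA@r0)
    }
  }
})

test_that("correction shrinks the across-level spread of clean-air curves", {
  models <- tinyModels(noiseCv = 0.01)
  cs <- tinyCalibration(models)
  spread <- function(curves) {
    m <- vapply(curves, function(x) {
      dur <- curveTimes(x) >= TINY_BOUNDS[1] & curveTimes(x) < TINY_BOUNDS[2]
      mean(abs(resistance(x)[dur]))
    }, 1)
    diff(range(m))
  }
  for (cfg in list(list(strat = "diff", bmode = "subtract"),
                   list(strat = "ratio", bmode = "divide"))) {
    k <- buildSurface(cs, "chA", cfg$strat)
    raw <- list(); corr <- list()
    for (f in calibrationLevels(cs)) {
      b <- removeBaseline(
        sensorCurves(calibrationReplicates(cs, f)[[1]])[["chA"]], cfg$bmode)
      raw[[length(raw) + 1L]] <- b
      corr[[length(corr) + 1L]] <- applyCorrection(b, k, f)
    }
    expect_lt(spread(corr), spread(raw))
  }
})

test_that("ratio surfaces and ratio-corrected curves stay positive", {
  models <- tinyModels(noiseCv = 0.02)
  cs <- tinyCalibration(models)
  k <- buildSurface(cs, "chA", "ratio")
  expect_true(all(kValues(k) > 0))
  samp <- removeBaseline(
    simulateCurve(models$chA, 0.9, 0.4, TINY_BOUNDS, 1, seed = 2), "divide")
  expect_true(all(resistance(applyCorrection(samp, k, 0.4)) > 0))
})

test_that("strategy/baseline-mode mismatch is rejected", {
  models <- tinyModels(noiseCv = 0)
  cs <- tinyCalibration(models)
  k <- buildSurface(cs, "chA", "diff")
  wrong <- removeBaseline(sensorCurves(tinyMeasurement(models))[["chA"]], "divide")
  expect_error(applyCorrection(wrong, k, 0.3), "does not match")
})

test_that("surfaces survive CSV + JSON round trip", {
  cs <- tinyCalibration(tinyModels(noiseCv = 0.01))
  ss <- buildSurfaces(cs, "ratio")
  p <- withr::local_tempfile(fileext = ".csv")
  writeSurfaces(ss, p)
  ss2 <- readSurfaces(p)
  expect_equal(names(ss2), names(ss))
  expect_equal(surfaceStrategy(ss2[[1]]), "ratio")
  expect_equal(kValues(ss2[["chA"]]), kValues(ss[["chA"]]),
               ignore_attr = TRUE, tolerance = 1e-9)
})
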