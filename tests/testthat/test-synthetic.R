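test_that("null stimulus gives a flat curve at baseline resistance", {
  mdl <- tinyModels(noiseCv = 0)[[1]]
  c0 <- simulateCurve(mdl, 0, 0.21, TINY_BOUNDS, 1)
  expect_equal(resistance(c0), rep(1e4, 121))
})

test_that("during-phase minimum approaches r0 (1 - alphaVc) at unit load", {
  mdl <- tinyModels(noiseCv = 0)[[1]]     # tauOn = 5 s, during lasts 50 s
  c1 <- simulateCurve(mdl, 1, 0.21, TINY_BOUNDS, 1)
  dur <- slicePhase(c1, "during")
  expect_equal(min(resistance(dur)), 1e4 * (1 - 0.5 * (1 - exp(-49 / 5))))
  expect_equal(min(resistance(dur)), 1e4 * 0.5, tolerance = 1e-4)
})

test_that("curves are deterministic per seed and vary across seeds", {
  mdl <- tinyModels(noiseCv = 0.05)[[1]]
  a <- simulateCurve(mdl, 1, 0.3, TINY_BOUNDS, 1, seed = 4)
  b <- simulateCurve(mdl, 1, 0.3, TINY_BOUNDS, 1, seed = 4)
  c <- simulateCurve(mdl, 1, 0.3, TINY_BOUNDS, 1, seed = 5)
  expect_identical(resistance(a), resistance(b))
  expect_false(identical(resistance(a), resistance(c)))
})

test_that("excessive VC load is rejected before producing non-physical curves", {
  mdl <- tinyModels(noiseCv = 0)[[1]]     # alphaVc = 0.5
  expect_error(simulateCurve(mdl, 2, 0.21, TINY_BOUNDS, 1), "zero")
})

test_that("calibration series matches the 6-level x 3-replicate design", {
  cs <- tinyCalibration(tinyModels(noiseCv = 0))
  expect_equal(calibrationLevels(cs), c(0.21, 0.25, 0.30, 0.35, 0.40, 0.50))
  expect_equal(sum(vapply(calibrationLevels(cs), function(lv)
    length(calibrationReplicates(cs, lv)), 1L)), 18L)
  # noiseless replicates are identical
  reps <- calibrationReplicates(cs, 0.30)
  expect_identical(resistance(sensorCurves(reps[[1]])[[1]]),
                   resistance(sensorCurves(reps[[2]])[[1]]))
})

test_that("additive clean-air plateau shift equals r0 betaO2 (f - 0.21)", {
  models <- tinyModels(noiseCv = 0, o2Mode = "additive")
  cs <- tinyCalibration(models)
  for (f in c(0.30, 0.50)) {
    mf <- sensorCurves(calibrationReplicates(cs, f)[[1]])[["chA"]]
    m21 <- sensorCurves(calibrationReplicates(cs, 0.21)[[1]])[["chA"]]
    dur <- curveTimes(mf) >= TINY_BOUNDS[1] & curveTimes(mf) < TINY_BOUNDS[2]
    g <- 1 - exp(-(curveTimes(mf)[dur] - TINY_BOUNDS[1]) / 5)
    expect_equal(resistance(mf)[dur] - resistance(m21)[dur],
                 1e4 * 0.8 * (f - 0.21) * g)
  }
})

test_that("cohort realisation matches the study design and physiology bounds", {
  spec <- cohortSpec(seed = 3)
  co <- simulateCohort(spec, models = tinyModels(noiseCv = 0.01),
                       phaseBounds = TINY_BOUNDS, rateHz = 1)
  expect_length(co$measurements, 152L)          # (9 + 10) animals x 8 timepoints
  ph <- co$physio
  expect_equal(nrow(ph), 152L)
  expect_true(all(ph$DBP <= ph$MAP & ph$MAP <= ph$SBP))
  expect_true(all(ph[c("DBP", "MAP", "SBP", "HR", "T")] > 0))
  expect_gt(mean(ph$MAP[ph$group == "control"]), 80)
  lps180 <- ph$MAP[ph$group == "LPS" & ph$timepoint == "t180"]
  expect_true(mean(lps180) > 40 && mean(lps180) < 60)
  # FiO2 recorded consistently in measurements and physio records
  f1 <- vapply(co$measurements, fio2, 1)
  expect_equal(f1, ph$fio2)
  # reproducibility
  co2 <- simulateCohort(spec, models = tinyModels(noiseCv = 0.01),
                        phaseBounds = TINY_BOUNDS, rateHz = 1)
  expect_identical(resistance(sensorCurves(co$measurements[[40]])[[1]]),
                   resistance(sensorCurves(co2$measurements[[40]])[[1]]))
  expect_identical(co$physio, co2$physio)
})

test_that("a zero-effect cohort carries no group signal (permutation oracle)", {
  co <- simulateCohort(nullCohortSpec(seed = 8, nControl = 8, nLps = 8),
                       models = tinyModels(noiseCv = 0.01),
                       phaseBounds = TINY_BOUNDS, rateHz = 1)
  ft <- asFeatureDf(buildFeatureTable(co$measurements, "none"))
  sub <- ft[ft$timepoint == "t180", ]
  stat <- function(lab) abs(diff(tapply(sub$chA.amplitude, lab, mean)))
  obs <- stat(sub$group)
  perm <- withr::with_seed(17, replicate(199, stat(sample(sub$group))))
  expect_gt(mean(c(obs, perm) >= obs), 0.05)   # observed not in the extreme tail
})
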