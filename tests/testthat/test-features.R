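test_that("null deviation curve yields all-zero features", {
  m <- constMeasurement(5e3)
  m@curves <- lapply(m@curves, removeBaseline, mode = "subtract")
  fv <- extractFeatures(m)
  expect_true(all(fv[grep("amplitude|auc|slope", names(fv))] == 0))
})

test_that("triangular deviation matches the hand-computed oracle", {
  # dev = 0,-1,...,-5,...,-1,0 at 1 Hz; phases (1, 8, 10)
  t <- 0:10
  dev <- c(0, -1, -2, -3, -4, -5, -4, -3, -2, -1, 0)
  c1 <- sensorCurve("chA", t, 100 + dev, c(1, 8, 10))
  m <- eNoseMeasurement("A", "LPS", "t5", 0.3,
                        list(removeBaseline(c1, "subtract")))
  fv <- extractFeatures(m, window = c("before", "during", "after"))
  expect_equal(fv[["chA.amplitude"]], 5)
  expect_equal(fv[["chA.auc"]], 25)              # trapezoid by hand
  expect_equal(fv[["chA.max_slope_on"]], -1)     # steepest drop, per second
  expect_equal(fv[["chA.max_slope_off"]], 1)
  expect_equal(fv[["chA.t_to_extremum"]], 4)     # extremum at t=5, onset at t=1
  expect_equal(fv[["chA.recovery_fraction"]], 0)
})

test_that("features are homogeneous in curve scale where they should be", {
  models <- tinyModels(noiseCv = 0)
  b <- removeBaseline(sensorCurves(tinyMeasurement(models))[["chA"]], "subtract")
  m1 <- eNoseMeasurement("A", "LPS", "t5", 0.3, list(b))
  b3 <- b
  b3@resistance <- 3 * b@resistance
  m3 <- eNoseMeasurement("A", "LPS", "t5", 0.3, list(b3))
  f1 <- extractFeatures(m1)
  f3 <- extractFeatures(m3)
  expect_equal(f3[["chA.amplitude"]], 3 * f1[["chA.amplitude"]])
  expect_equal(f3[["chA.auc"]], 3 * f1[["chA.auc"]])
  expect_equal(f3[["chA.t_to_extremum"]], f1[["chA.t_to_extremum"]])
  expect_equal(f3[["chA.recovery_fraction"]], f1[["chA.recovery_fraction"]])
})

test_that("feature extraction ignores measurement metadata", {
  models <- tinyModels(noiseCv = 0)
  m1 <- tinyMeasurement(models, animal = "A1", group = "LPS", timepoint = "t60")
  m2 <- tinyMeasurement(models, animal = "Z9", group = "control", timepoint = "t5")
  b <- function(m) {
    m@curves <- lapply(m@curves, removeBaseline, mode = "subtract")
    m
  }
  expect_equal(extractFeatures(b(m1)), extractFeatures(b(m2)))
})

.iqrToy <- function(vals, tp = "t5") {
  v <- cbind(f1 = vals)
  rownames(v) <- sprintf("A%02d.%s", seq_along(vals), tp)
  featureTable(v, data.frame(animalId = sprintf("A%02d", seq_along(vals)),
                             group = "control", timepoint = tp, fio2 = 0.3))
}

test_that("Tukey screening masks exactly the planted outlier", {
  ft <- .iqrToy(c(1:9, 100))
  out <- iqrScreen(ft, fenceMult = 1.5)
  expect_equal(sum(featureMask(out$table)), 1L)
  expect_true(featureMask(out$table)[10, "f1"])
  expect_equal(nrow(out$report), 1L)
  expect_equal(out$report$value, 100)
  # imputed with the in-fence median
  expect_equal(featureValues(out$table)[10, "f1"], 5)
})

test_that("degenerate and infinite-fence groups mask nothing", {
  same <- iqrScreen(.iqrToy(rep(4, 8)), fenceMult = 1.5)
  expect_equal(sum(featureMask(same$table)), 0L)
  wide <- iqrScreen(.iqrToy(c(1:9, 100)), fenceMult = 1e9)
  expect_equal(sum(featureMask(wide$table)), 0L)
  expect_equal(featureValues(wide$table)[, "f1"], c(1:9, 100), ignore_attr = TRUE)
})

test_that("screening is idempotent and counts match the mask", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      vals <- stats::rnorm(16)
      vals[sample(16, 1)] <- 12          # one gross outlier
      ft <- .iqrToy(vals)
      s1 <- iqrScreen(ft, fenceMult = 1.5)
      expect_equal(nrow(s1$report), sum(featureMask(s1$table)))
      s2 <- iqrScreen(s1$table, fenceMult = 1.5)
      expect_equal(sum(featureMask(s2$table)), sum(featureMask(s1$table)))
    }
  })
})

test_that("small cell groups are left unscreened", {
  out <- iqrScreen(.iqrToy(c(1, 2, 100)), fenceMult = 1.5)
  expect_equal(sum(featureMask(out$table)), 0L)
})

test_that("feature tables carry labels and unique sample keys", {
  models <- tinyModels(noiseCv = 0.01)
  co <- simulateCohort(cohortSpec(nControl = 2, nLps = 2, seed = 4),
                       models, TINY_BOUNDS, 1)
  ft <- buildFeatureTable(co$measurements, "none")
  expect_equal(nrow(featureValues(ft)), 32L)
  expect_equal(ncol(featureValues(ft)), 12L)     # 2 channels x 6 features
  expect_false(anyDuplicated(rownames(featureValues(ft))) > 0)
  expect_true(all(sampleInfo(ft)$group %in% c("control", "LPS")))
  expect_true(all(is.finite(featureValues(ft))))
})
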