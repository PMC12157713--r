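test_that("cumulative assembly spans t5 through the target and excludes t0", {
  df <- blobTable(nPerGroup = 2, timepoints = c("t0", "t5", "t30", "t60"))
  cum <- assembleCumulative(df, "t60")
  expect_equal(sort(unique(cum$timepoint)), c("t30", "t5", "t60"))
  expect_equal(nrow(cum), 12L)                    # 4 animals x 3 timepoints
  expect_equal(unique(assembleCumulative(df, "t5")$timepoint), "t5")
  expect_error(assembleCumulative(df, "t0"), "t0")
  expect_error(assembleCumulative(df, "t45"), "unknown timepoint")
  withT0 <- assembleCumulative(df, "t60", includeT0 = TRUE)
  expect_equal(nrow(withT0), 16L)
})

test_that("z-scoring maps the training set to mean 0 / SD 1 and reuses train stats", {
  x <- matrix(stats::rnorm(60, 5, 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sc <- zscoreFit(x)
  z <- zscoreApply(sc, x)
  expect_equal(colMeans(z), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 3), ignore_attr = TRUE)
  # row at the train mean maps to zero
  expect_equal(as.numeric(zscoreApply(sc, t(colMeans(x)))), rep(0, 3))
  # constant column warns and maps to 0
  x2 <- cbind(x, k = 7)
  expect_warning(sc2 <- zscoreFit(x2), "zero-SD")
  expect_equal(unname(zscoreApply(sc2, x2)[, "k"]), rep(0, 20))
})

test_that("PCA projection is orthonormal, sign-fixed and isometric at full rank", {
  withr::with_seed(5, {
    x <- matrix(stats::rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  })
  pr <- pcaFit(x, 3)
  expect_equal(t(pr$loadings) %*% pr$loadings, diag(3), ignore_attr = TRUE)
  expect_true(all(diff(pr$explained) <= 1e-12))
  for (j in 1:3) expect_gt(pr$loadings[which.max(abs(pr$loadings[, j])), j], 0)
  # full-rank scores preserve pairwise distances
  s <- pcaApply(pr, x)
  expect_equal(as.numeric(dist(s)), as.numeric(dist(x)), tolerance = 1e-12)
  # agreement with prcomp up to the sign convention
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(abs(unclass(s)), abs(pc$x[, 1:3]), ignore_attr = TRUE)
  # rank-1 data: one component explains everything
  line <- cbind(a = 1:6, b = 2 * (1:6))
  expect_equal(pcaFit(line, 1)$explained, 1)
  expect_error(pcaFit(x, 5), "exceeds")
})

test_that("LOO is perfect on widely separated groups and covers each unit once", {
  df <- blobTable(nPerGroup = 6, timepoints = c("t5", "t30", "t60"),
                  sep = 6, noiseSd = 0.05)
  for (cls in c("logistic", "tree")) {
    spec <- modelSpec("enose_raw", classifier = cls, screenOutliers = FALSE)
    res <- looEvaluate(df, spec, timepoint = "t30")
    expect_equal(res$result$accuracy, 100)
    expect_equal(res$result$n, nrow(df))
  }
  # every sample predicted exactly once; folds = units
  res <- looEvaluate(df, modelSpec("physio"), unit = "animal")
  expect_equal(sort(table(res$predictions$fold)), sort(table(df$animalId)),
               ignore_attr = TRUE)
  expect_equal(length(unique(res$predictions$fold)), length(unique(df$animalId)))
})

test_that("LOO equals a from-scratch enumeration of all folds (oracle)", {
  df <- blobTable(nPerGroup = 6, timepoints = "t5", sep = 2.5, seed = 9)
  spec <- modelSpec("physio", nComponents = 2, screenOutliers = FALSE)
  mine <- looEvaluate(df, spec, unit = "sample")
  feats <- paste0("f", 1:4)
  # independent oracle: base scale(), prcomp() and weighted glm per fold
  oracle <- vapply(seq_len(nrow(df)), function(i) {
    tr <- df[-i, ]; te <- df[i, ]
    sc <- scale(tr[, feats])
    pc <- stats::prcomp(sc, center = TRUE, scale. = FALSE)
    str <- pc$x[, 1:2]
    ste <- scale(te[, feats], center = attr(sc, "scaled:center"),
                 scale = attr(sc, "scaled:scale")) %*% pc$rotation[, 1:2]
    y <- factor(tr$group, levels = c("control", "LPS"))
    w <- as.numeric(0.5 * length(y) / table(y)[as.character(y)])
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = data.frame(y = y, str),
                                       weights = w))
    p <- suppressWarnings(stats::predict(fit, data.frame(ste), type = "response"))
    ifelse(p > 0.5, "LPS", "control")
  }, character(1))
  expect_equal(mine$predictions$predicted, unname(oracle))
  tp <- sum(df$group == "LPS" & oracle == "LPS")
  tn <- sum(df$group == "control" & oracle == "control")
  expect_equal(mine$result$tp, tp)
  expect_equal(mine$result$tn, tn)
})

test_that("no leakage: fold models depend only on training rows", {
  df <- blobTable(nPerGroup = 4, sep = 3, seed = 3)
  spec <- modelSpec("enose_raw", screenOutliers = TRUE)
  res <- looEvaluate(df, spec)
  u <- unique(df$animalId)[2]
  # manually re-fit the fold without u using package stage functions
  feats <- paste0("f", 1:4)
  tr <- df[df$animalId != u, ]
  te <- df[df$animalId == u, ]
  st <- iqrStats(tr, fenceMult = 1.5)
  # apply screen to train and test exactly as the fold does
  trv <- as.matrix(tr[, feats]); tev <- as.matrix(te[, feats])
  for (i in seq_len(nrow(st))) {
    s <- st[i, ]
    r1 <- which(tr$timepoint == s$timepoint)
    b1 <- trv[r1, s$feature] < s$lo | trv[r1, s$feature] > s$hi
    trv[r1[b1], s$feature] <- s$impute
    r2 <- which(te$timepoint == s$timepoint)
    b2 <- tev[r2, s$feature] < s$lo | tev[r2, s$feature] > s$hi
    tev[r2[b2], s$feature] <- s$impute
  }
  sc <- suppressWarnings(zscoreFit(trv))
  pr <- pcaFit(zscoreApply(sc, trv), 2)
  fit <- septanose:::.fitClassifier(pcaApply(pr, zscoreApply(sc, trv)),
                                    tr$group, spec)
  pred <- septanose:::.predictClassifier(fit, pcaApply(pr, zscoreApply(sc, tev)))
  expect_equal(res$predictions$predicted[res$predictions$fold == u],
               unname(pred))
})

test_that("LOO on permuted labels stays near chance", {
  withr::with_seed(21, {
    df <- blobTable(nPerGroup = 10, timepoints = c("t5", "t30"), sep = 6)
    df$group <- sample(df$group)   # break the label-feature link
  })
  res <- looEvaluate(df, modelSpec("physio"), unit = "sample")
  band <- 100 * stats::qbinom(c(0.025, 0.975), nrow(df), 0.5) / nrow(df)
  expect_gte(res$result$accuracy, band[1])
  expect_lte(res$result$accuracy, band[2])
})

test_that("metrics and Wald intervals match closed-form arithmetic", {
  perfect <- metricsWithCI(10, 10, 0, 0)
  expect_equal(perfect$accuracy, 100)
  expect_equal(c(perfect$acc_lo, perfect$acc_hi), c(100, 100))
  m <- metricsWithCI(16, 0, 0, 4)     # p-hat = 0.8, n = 20
  expect_equal(round(c(m$acc_lo, m$acc_hi), 1), c(62.5, 97.5))
  expect_equal(m$acc_lo, 100 * (0.8 - stats::qnorm(0.975) * sqrt(0.8 * 0.2 / 20)))
  # zero denominator -> missing, not zero
  noPos <- metricsWithCI(0, 12, 3, 0)
  expect_true(is.na(noPos$sensitivity))
  expect_false(is.na(noPos$specificity))
  # point estimate always inside its CI
  some <- metricsWithCI(7, 6, 3, 4)
  expect_true(some$acc_lo <= some$accuracy && some$accuracy <= some$acc_hi)
  wil <- metricsWithCI(16, 0, 0, 4, ciMethod = "wilson")
  expect_lt(wil$acc_hi, m$acc_hi)     # Wilson pulls toward 1/2
})

test_that("physio trajectories are zero for static data and linear in translations", {
  withr::with_seed(8, {
    base <- data.frame(animalId = sprintf("A%d", 1:8),
                       group = rep(c("control", "LPS"), each = 4),
                       MAP = stats::rnorm(8, 85, 5), DBP = stats::rnorm(8, 70, 5),
                       SBP = stats::rnorm(8, 110, 6), HR = stats::rnorm(8, 90, 8),
                       T = stats::rnorm(8, 38.4, 0.3))
  })
  static <- rbind(cbind(timepoint = "t0", base), cbind(timepoint = "t30", base))
  tr <- physioTrajectories(static)
  expect_true(all(abs(tr$displacements$modulus) < 1e-10))
  # translate the LPS group by v at t30
  v <- c(MAP = -20, DBP = -10, SBP = -15, HR = 25, T = 1)
  moved <- static
  i <- moved$timepoint == "t30" & moved$group == "LPS"
  moved[i, names(v)] <- sweep(moved[i, names(v)], 2, -v)
  tr2 <- physioTrajectories(moved)
  gm <- tr2$groupMeans
  expected <- as.numeric((v / tr2$scaler$sd) %*% tr2$projection$loadings)
  got <- as.numeric(gm[gm$group == "LPS" & gm$timepoint == "t30",
                       paste0("dPC", seq_along(expected))])
  expect_equal(got, expected, tolerance = 1e-8)
  expect_true(all(abs(gm[gm$group == "control", "modulus"]) < 1e-10))
  # group means come from per-animal vectors
  expect_equal(sum(tr2$displacements$timepoint == "t30" &
                   tr2$displacements$group == "LPS"), 4L)
  # missing t0 -> excluded with warning
  expect_warning(physioTrajectories(moved[-1, ]), "without a t0")
})

test_that("LOO and runStudy are deterministic given the seed", {
  models <- tinyModels(noiseCv = 0.01)
  co <- simulateCohort(cohortSpec(nControl = 3, nLps = 3, seed = 6),
                       models, TINY_BOUNDS, 1)
  cal <- tinyCalibration(models)
  s1 <- runStudy(co$measurements, co$physio, cal, timepoints = c("t5", "t30"),
                 seed = 2)
  s2 <- runStudy(co$measurements, co$physio, cal, timepoints = c("t5", "t30"),
                 seed = 2)
  expect_identical(s1$results, s2$results)
  expect_equal(nrow(s1$details), 8L)             # 2 timepoints x 4 variants
  expect_error(runStudy(co$measurements, co$physio, cal,
                        variants = "enose_quadratic"), "unknown variant")
})
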