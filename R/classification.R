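# Per-timepoint classification: cumulative assembly, z-score + PCA
# transforms fitted on training data only, leave-one-out evaluation with
# Wald confidence intervals, and the physiological PCA-trajectory summary.

#' ModelSpec: configuration of one classification variant
#'
#' Variants: \code{physio} (5 PCA components + logistic regression on MAP,
#' DBP, SBP, HR, T), \code{enose_raw} / \code{enose_kdiff} /
#' \code{enose_kratio} (2 PCA components + depth-3 decision tree on curve
#' features, differing only in the FiO2 correction applied before feature
#' extraction). Defaults follow those pairings; both classifier and
#' dimensionality are overridable.
#'
#' @slot variant variant label.
#' @slot nComponents PCA dimensionality.
#' @slot classifier \code{"logistic"} or \code{"tree"}.
#' @slot treeMaxDepth maximum decision-tree depth.
#' @slot screenOutliers run the IQR screen inside each training fold.
#' @slot fenceMult Tukey fence multiplier for the screen.
#' @slot seed integer seed.
#' @export
setClass("ModelSpec",
  representation(variant = "character", nComponents = "numeric",
                 classifier = "character", treeMaxDepth = "numeric",
                 screenOutliers = "logical", fenceMult = "numeric",
                 seed = "numeric"))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!(object@variant %in% c("physio", "enose_raw", "enose_kdiff", "enose_kratio")))
    msgs <- c(msgs, "unknown variant")
  if (!(object@classifier %in% c("logistic", "tree")))
    msgs <- c(msgs, "classifier must be 'logistic' or 'tree'")
  if (object@nComponents < 1) msgs <- c(msgs, "nComponents must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ModelSpec
#'
#' @param variant one of \code{"physio"}, \code{"enose_raw"},
#'   \code{"enose_kdiff"}, \code{"enose_kratio"}.
#' @param nComponents PCA components (default 5 for physio, 2 for e-Nose).
#' @param classifier default logistic for physio, tree for e-Nose.
#' @param treeMaxDepth decision-tree depth cap (default 3).
#' @param screenOutliers IQR screen inside folds (default TRUE for e-Nose).
#' @param fenceMult Tukey fence multiplier (default 1.5).
#' @param seed integer seed (default 1).
#' @return A validated \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(variant,
                      nComponents = if (variant == "physio") 5 else 2,
                      classifier = if (variant == "physio") "logistic" else "tree",
                      treeMaxDepth = 3,
                      screenOutliers = variant != "physio",
                      fenceMult = 1.5, seed = 1) {
  new("ModelSpec", variant = variant, nComponents = nComponents,
      classifier = classifier, treeMaxDepth = treeMaxDepth,
      screenOutliers = screenOutliers, fenceMult = fenceMult, seed = seed)
}

.metaCols <- c("animalId", "group", "timepoint", "fio2")

.featCols <- function(df) setdiff(names(df), .metaCols)

#' Flatten a FeatureTable to a classification data.frame
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @return data.frame with metadata columns plus one column per feature.
#' @export
asFeatureDf <- function(ft) .asFeatureDf(ft)

#' Assemble the cumulative per-timepoint data set
#'
#' The model at timepoint t is trained on all samples from t5 through t;
#' the pre-administration baseline t0 is excluded (optionally included via
#' \code{includeT0}).
#'
#' @param df classification data.frame (one row per animal-timepoint sample).
#' @param timepoint target timepoint (not t0 unless \code{includeT0}).
#' @param timepoints ordered study timepoints.
#' @param includeT0 include baseline rows (default FALSE).
#' @return The row subset for timepoints t5 .. target.
#' @export
assembleCumulative <- function(df, timepoint, timepoints = STUDY_TIMEPOINTS,
                               includeT0 = FALSE) {
  i <- match(timepoint, timepoints)
  if (is.na(i)) stop("unknown timepoint: '", timepoint, "'")
  first <- if (includeT0) 1L else 2L
  if (i < first)
    stop("baseline t0 is excluded from cumulative sets; set includeT0 = TRUE to include it")
  keep <- timepoints[first:i]
  df[df$timepoint %in% keep, , drop = FALSE]
}

# ---- transforms ------------------------------------------------------------

#' Z-score scaler fitted on training data
#'
#' \code{zscoreFit} learns per-column means and SDs; \code{zscoreApply} maps
#' any table with those statistics, so a test set is transformed with the
#' training statistics. Zero-SD (constant) training columns transform to 0,
#' with a warning at fit time.
#'
#' @param x numeric matrix or data.frame of feature columns.
#' @return \code{zscoreFit}: a scaler object; \code{zscoreApply}: the
#'   transformed matrix.
#' @export
zscoreFit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("zscoreFit needs >= 2 rows")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    warning("zero-SD column(s) map to 0: ", paste(colnames(x)[zero], collapse = ", "))
    sd[zero] <- 1
  }
  structure(list(mean = mu, sd = sd, zero = zero), class = "septanoseScaler")
}

#' @rdname zscoreFit
#' @param scaler object from \code{zscoreFit}.
#' @export
zscoreApply <- function(scaler, x) {
  x <- as.matrix(x)[, names(scaler$mean), drop = FALSE]
  z <- sweep(sweep(x, 2L, scaler$mean), 2L, scaler$sd, `/`)
  z[, scaler$zero] <- 0
  z
}

#' Principal component projection fitted on training data
#'
#' Singular-value decomposition of the column-centered training matrix.
#' Loadings are orthonormal with explained variance nonincreasing; signs are
#' fixed deterministically by making each loading's largest-magnitude element
#' positive.
#'
#' @param x numeric training matrix.
#' @param nComponents number of components (<= min(rows - 1, columns)).
#' @return \code{pcaFit}: projection object with elements \code{center},
#'   \code{loadings}, \code{explained} (variance fractions);
#'   \code{pcaApply}: score matrix with columns \code{PC1..}.
#' @export
pcaFit <- function(x, nComponents) {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (nComponents > kmax)
    stop("nComponents = ", nComponents, " exceeds min(rows - 1, cols) = ", kmax)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  load <- sv$v[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(nComponents))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(center = ctr, loadings = load,
                 explained = ev[seq_len(nComponents)]),
            class = "septanosePca")
}

#' @rdname pcaFit
#' @param projection object from \code{pcaFit}.
#' @export
pcaApply <- function(projection, x) {
  x <- as.matrix(x)[, names(projection$center), drop = FALSE]
  sweep(x, 2L, projection$center) %*% projection$loadings
}

# ---- classifiers -----------------------------------------------------------

# Both classifiers train with balanced class priors: under leave-one-animal-
# out the training fold is always depleted in the held-out animal's class
# (and the study groups are 9 vs 10 to begin with), and an unbalanced prior
# systematically biases every held-out prediction toward the other class.
.fitClassifier <- function(scores, labels, spec) {
  y <- factor(labels, levels = c("control", "LPS"))
  df <- data.frame(.y = y, scores, check.names = FALSE)
  if (spec@classifier == "logistic") {
    w <- 0.5 * length(y) / table(y)[as.character(y)]
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                weights = as.numeric(w)))
  } else {
    rpart::rpart(.y ~ ., data = df, method = "class",
                 parms = list(prior = c(0.5, 0.5)),
                 control = rpart::rpart.control(maxdepth = spec@treeMaxDepth,
                                                minsplit = 20, minbucket = 7,
                                                cp = 0.01, xval = 0))
  }
}

.predictClassifier <- function(fit, scores) {
  df <- as.data.frame(scores)
  p <- if (inherits(fit, "rpart")) stats::predict(fit, df, type = "prob")[, "LPS"]
       else suppressWarnings(stats::predict(fit, df, type = "response"))
  ifelse(p > 0.5, "LPS", "control")  # tie -> control, deterministic
}

# Matrix-form Tukey-fence screen used inside LOO folds (same statistics as
# iqrStats/iqrScreen, vectorised per timepoint for speed).
.iqrFences <- function(values, tps, fenceMult, minN = 4L) {
  lapply(split(seq_len(nrow(values)), tps), function(rows) {
    if (length(rows) < minN) return(NULL)
    v <- values[rows, , drop = FALSE]
    q <- apply(v, 2L, stats::quantile, probs = c(0.25, 0.75),
               names = FALSE, type = 7)
    iqr <- q[2, ] - q[1, ]
    lo <- q[1, ] - fenceMult * iqr
    hi <- q[2, ] + fenceMult * iqr
    imp <- vapply(seq_len(ncol(v)), function(j) {
      x <- v[, j]
      stats::median(x[x >= lo[j] & x <= hi[j]])
    }, numeric(1))
    list(lo = lo, hi = hi, impute = imp)
  })
}

.applyFences <- function(values, tps, fences) {
  for (tp in names(fences)) {
    f <- fences[[tp]]
    if (is.null(f)) next
    rows <- which(tps == tp)
    if (!length(rows)) next
    v <- values[rows, , drop = FALSE]
    lo <- matrix(f$lo, nrow(v), ncol(v), byrow = TRUE)
    hi <- matrix(f$hi, nrow(v), ncol(v), byrow = TRUE)
    im <- matrix(f$impute, nrow(v), ncol(v), byrow = TRUE)
    bad <- v < lo | v > hi
    v[bad] <- im[bad]
    values[rows, ] <- v
  }
  values
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics with 95% confidence intervals
#'
#' Accuracy, sensitivity (LPS = positive class) and specificity as percents,
#' each with a 95% Wald interval p +/- z sqrt(p(1-p)/n) clipped to [0, 100]
#' (Wilson intervals available via \code{ciMethod}). A zero denominator
#' (e.g. no positive truth rows for sensitivity) yields NA, not 0.
#'
#' @param tp,tn,fp,fn confusion counts (LPS positive).
#' @param timepoint,variant optional labels copied into the result.
#' @param ciMethod \code{"wald"} (default) or \code{"wilson"}.
#' @param level confidence level (default 0.95).
#' @return One-row data.frame with counts, metrics and CI bounds (percent).
#' @export
metricsWithCI <- function(tp, tn, fp, fn, timepoint = NA_character_,
                          variant = NA_character_,
                          ciMethod = c("wald", "wilson"), level = 0.95) {
  ciMethod <- match.arg(ciMethod)
  n <- tp + tn + fp + fn
  if (n <= 0) stop("empty confusion: n must be > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  one <- function(x, d) {
    if (d == 0) return(c(NA_real_, NA_real_, NA_real_))
    p <- x / d
    ci <- if (ciMethod == "wald") {
      se <- sqrt(p * (1 - p) / d)
      c(p - z * se, p + z * se)
    } else {
      den <- 1 + z^2 / d
      ctr <- (p + z^2 / (2 * d)) / den
      hw <- z * sqrt(p * (1 - p) / d + z^2 / (4 * d^2)) / den
      c(ctr - hw, ctr + hw)
    }
    100 * c(p, max(0, ci[1]), min(1, ci[2]))
  }
  acc <- one(tp + tn, n); sens <- one(tp, tp + fn); spc <- one(tn, tn + fp)
  data.frame(variant = variant, timepoint = timepoint, n = n,
             tp = tp, tn = tn, fp = fp, fn = fn,
             accuracy = acc[1], acc_lo = acc[2], acc_hi = acc[3],
             sensitivity = sens[1], sens_lo = sens[2], sens_hi = sens[3],
             specificity = spc[1], spec_lo = spc[2], spec_hi = spc[3])
}

# ---- leave-one-out evaluation ----------------------------------------------

#' Leave-one-out evaluation of one model variant
#'
#' For each held-out unit (an animal by default, so an animal's multiple
#' cumulative rows never leak into its own training fold) the full pipeline —
#' optional in-fold IQR screen, z-score, PCA, classifier — is re-fitted on
#' the remaining rows and the held-out rows are predicted. Predictions are
#' pooled over folds and summarised with \code{\link{metricsWithCI}}.
#' Training folds missing a class are flagged and excluded from pooling.
#'
#' @param df classification data.frame: metadata columns \code{animalId},
#'   \code{group}, \code{timepoint} (and optionally \code{fio2}) plus numeric
#'   feature columns.
#' @param spec a \linkS4class{ModelSpec}.
#' @param unit \code{"animal"} (default) or \code{"sample"}.
#' @param timepoint label copied into the result row.
#' @return list with \code{result} (one-row metrics data.frame),
#'   \code{predictions} (per-row truth/prediction/fold) and
#'   \code{flaggedFolds}.
#' @export
looEvaluate <- function(df, spec, unit = c("animal", "sample"),
                        timepoint = NA_character_) {
  unit <- match.arg(unit)
  validObject(spec)
  feats <- .featCols(df)
  vals <- as.matrix(df[, feats, drop = FALSE])
  units <- if (unit == "animal") unique(df$animalId) else seq_len(nrow(df))
  if (length(units) < 2L) stop("leave-one-out needs >= 2 units")
  preds <- list(); flagged <- character(0)
  withr::with_seed(as.integer(spec@seed), {
    for (u in units) {
      testIdx <- if (unit == "animal") which(df$animalId == u) else u
      vtr <- vals[-testIdx, , drop = FALSE]
      vte <- vals[testIdx, , drop = FALSE]
      if (length(unique(df$group[-testIdx])) < 2L) {
        flagged <- c(flagged, as.character(u))
        next
      }
      if (spec@screenOutliers) {
        fences <- .iqrFences(vtr, df$timepoint[-testIdx], spec@fenceMult)
        vtr <- .applyFences(vtr, df$timepoint[-testIdx], fences)
        vte <- .applyFences(vte, df$timepoint[testIdx], fences)
      }
      scaler <- suppressWarnings(zscoreFit(vtr))
      # PCA dimensionality is capped at the training fold's capacity
      kEff <- min(spec@nComponents, nrow(vtr) - 1L, ncol(vtr))
      proj <- pcaFit(zscoreApply(scaler, vtr), kEff)
      fit <- .fitClassifier(pcaApply(proj, zscoreApply(scaler, vtr)),
                            df$group[-testIdx], spec)
      pr <- .predictClassifier(fit, pcaApply(proj, zscoreApply(scaler, vte)))
      preds[[length(preds) + 1L]] <- data.frame(
        animalId = df$animalId[testIdx], timepoint = df$timepoint[testIdx],
        truth = df$group[testIdx], predicted = pr, fold = as.character(u))
    }
  })
  if (!length(preds)) stop("no usable folds: every training fold missed a class")
  pooled <- do.call(rbind, preds)
  tp <- sum(pooled$truth == "LPS" & pooled$predicted == "LPS")
  tn <- sum(pooled$truth == "control" & pooled$predicted == "control")
  fp <- sum(pooled$truth == "control" & pooled$predicted == "LPS")
  fn <- sum(pooled$truth == "LPS" & pooled$predicted == "control")
  list(result = metricsWithCI(tp, tn, fp, fn, timepoint = timepoint,
                              variant = spec@variant),
       predictions = pooled, flaggedFolds = flagged)
}

# ---- physiological trajectories --------------------------------------------

#' PCA-space trajectories of the physiological state
#'
#' Z-score and PCA are fitted on the baseline (t0) records only; every later
#' record is projected into that fixed space. Each animal's displacement
#' vector at a timepoint is its projection minus its t0 projection (the
#' modulus-times-direction product); group summaries average the per-animal
#' displacement vectors and their moduli. Animals without a t0 record are
#' excluded with a warning.
#'
#' @param records physiological data.frame with columns \code{animalId},
#'   \code{group}, \code{timepoint} and the feature columns.
#' @param features feature columns (default MAP, DBP, SBP, HR, T).
#' @param nComponents PCA components (default 5, capped at the data rank).
#' @return list with \code{displacements} (per animal-timepoint) and
#'   \code{groupMeans} (per group-timepoint mean vector and mean modulus).
#' @export
physioTrajectories <- function(records, features = c("MAP", "DBP", "SBP", "HR", "T"),
                               nComponents = 5) {
  base <- records[records$timepoint == "t0", , drop = FALSE]
  noBase <- setdiff(unique(records$animalId), base$animalId)
  if (length(noBase)) {
    warning("excluding animal(s) without a t0 record: ", paste(noBase, collapse = ", "))
    records <- records[!records$animalId %in% noBase, , drop = FALSE]
    base <- records[records$timepoint == "t0", , drop = FALSE]
  }
  nComponents <- min(nComponents, nrow(base) - 1L, length(features))
  scaler <- suppressWarnings(zscoreFit(base[, features, drop = FALSE]))
  proj <- pcaFit(zscoreApply(scaler, base[, features, drop = FALSE]), nComponents)
  scores <- pcaApply(proj, zscoreApply(scaler, records[, features, drop = FALSE]))
  key <- paste(records$animalId, records$timepoint)
  base0 <- scores[match(paste(records$animalId, "t0"), key), , drop = FALSE]
  disp <- scores - base0
  colnames(disp) <- paste0("d", colnames(disp))
  out <- data.frame(animalId = records$animalId, group = records$group,
                    timepoint = records$timepoint, disp,
                    modulus = sqrt(rowSums(disp^2)))
  later <- out[out$timepoint != "t0", , drop = FALSE]
  gm <- stats::aggregate(later[, c(colnames(disp), "modulus")],
                         by = list(group = later$group, timepoint = later$timepoint),
                         FUN = mean)
  list(displacements = out, groupMeans = gm, projection = proj, scaler = scaler)
}

# ---- full study ------------------------------------------------------------

#' Run the full per-timepoint study over all model variants
#'
#' Builds the diff/ratio correction surfaces from the calibration series,
#' derives one feature table per e-Nose variant (no correction, k_diff,
#' k_ratio — identical otherwise), assembles the cumulative data set at every
#' requested timepoint and evaluates each variant by leave-one-out.
#'
#' @param measurements cohort e-Nose measurements.
#' @param physio physiological records data.frame.
#' @param calibration a \linkS4class{CalibrationSeries}.
#' @param variants variant labels to run (default all four).
#' @param timepoints evaluation timepoints (default t5 .. t180).
#' @param specs optional named list of \linkS4class{ModelSpec} overriding the
#'   per-variant defaults.
#' @param unit LOO unit (default \code{"animal"}).
#' @param seed integer seed stored into default model specs.
#' @return list with \code{results} (tidy long data.frame: variant,
#'   timepoint, metric, value, ci_lo, ci_hi, n), \code{details} (wide rows
#'   with confusion counts) and \code{tables} (the per-variant input tables).
#' @export
runStudy <- function(measurements, physio, calibration,
                     variants = c("physio", "enose_raw", "enose_kdiff", "enose_kratio"),
                     timepoints = setdiff(STUDY_TIMEPOINTS, "t0"),
                     specs = NULL, unit = "animal", seed = 1) {
  known <- c("physio", "enose_raw", "enose_kdiff", "enose_kratio")
  if (!all(variants %in% known))
    stop("unknown variant(s): ", paste(setdiff(variants, known), collapse = ", "))
  if (is.null(specs))
    specs <- stats::setNames(lapply(variants, modelSpec, seed = seed), variants)
  tables <- list()
  if ("physio" %in% variants) {
    tables$physio <- physio[, c("animalId", "group", "timepoint",
                                "MAP", "DBP", "SBP", "HR", "T")]
  }
  needDiff <- "enose_kdiff" %in% variants
  needRatio <- "enose_kratio" %in% variants
  if (needDiff) sDiff <- buildSurfaces(calibration, "diff")
  if (needRatio) sRatio <- buildSurfaces(calibration, "ratio")
  if ("enose_raw" %in% variants)
    tables$enose_raw <- asFeatureDf(buildFeatureTable(measurements, "none"))
  if (needDiff)
    tables$enose_kdiff <- asFeatureDf(buildFeatureTable(measurements, "diff", sDiff))
  if (needRatio)
    tables$enose_kratio <- asFeatureDf(buildFeatureTable(measurements, "ratio", sRatio))
  details <- list()
  for (v in variants) {
    for (tpt in timepoints) {
      cum <- assembleCumulative(tables[[v]], tpt)
      res <- looEvaluate(cum, specs[[v]], unit = unit, timepoint = tpt)
      details[[length(details) + 1L]] <- res$result
    }
  }
  details <- do.call(rbind, details)
  long <- do.call(rbind, lapply(c("accuracy", "sensitivity", "specificity"), function(m) {
    pre <- c(accuracy = "acc", sensitivity = "sens", specificity = "spec")[[m]]
    data.frame(variant = details$variant, timepoint = details$timepoint,
               metric = m, value = details[[m]],
               ci_lo = details[[paste0(pre, "_lo")]],
               ci_hi = details[[paste0(pre, "_hi")]], n = details$n)
  }))
  long <- long[order(match(long$variant, known),
                     match(long$timepoint, STUDY_TIMEPOINTS), long$metric), ]
  rownames(long) <- NULL
  list(results = long, details = details, tables = tables)
}
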