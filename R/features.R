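# Curve-shape feature extraction and Tukey-fence (IQR) outlier screening.

FEATURE_NAMES <- c("amplitude", "auc", "max_slope_on", "max_slope_off",
                   "t_to_extremum", "recovery_fraction")

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

.curveFeatures <- function(c, window, features) {
  pb <- c@phaseBounds
  t <- c@times
  dev <- c@resistance - c@resistance[1]  # deviation from the start value (0 or 1)
  inPhase <- list(before = t < pb[1],
                  during = t >= pb[1] & t < pb[2],
                  after  = t >= pb[2])
  win <- Reduce(`|`, inPhase[window])
  if (!any(win)) stop("empty window: no samples in phases ", paste(window, collapse = "+"))
  dt <- t[2] - t[1]
  aw <- abs(dev[win]); tw <- t[win]
  iExt <- which.max(aw)
  out <- c(
    amplitude = aw[iExt],
    auc = .trapz(tw, aw),
    max_slope_on = if (sum(inPhase$during) >= 2) min(diff(dev[inPhase$during]) / dt) else 0,
    max_slope_off = if (sum(inPhase$after) >= 2) max(diff(dev[inPhase$after]) / dt) else 0,
    t_to_extremum = tw[iExt] - pb[1],
    recovery_fraction = if (aw[iExt] > 0) abs(dev[max(which(win))]) / aw[iExt] else 0)
  out[features]
}

#' Extract curve-shape features from a measurement
#'
#' Reduces each (baseline-removed, optionally FiO2-corrected) channel curve
#' to shape/dynamics features measured on the deviation from the curve's
#' start value (0 for subtract-mode, 1 for divide-mode baseline removal):
#' \describe{
#'   \item{amplitude}{max |deviation| within the window.}
#'   \item{auc}{trapezoidal integral of |deviation| over the window.}
#'   \item{max_slope_on}{steepest negative first-difference per second in
#'     "during" (response onset).}
#'   \item{max_slope_off}{steepest positive first-difference per second in
#'     "after" (recovery).}
#'   \item{t_to_extremum}{seconds from "during" onset to the extremum.}
#'   \item{recovery_fraction}{|deviation| at the window end / amplitude.}
#' }
#'
#' @param m an \linkS4class{ENoseMeasurement} whose curves are baseline-removed.
#' @param window character subset of \code{c("before","during","after")}
#'   (default during + after).
#' @param features which features to compute (default all six).
#' @return Named numeric vector, names \code{<channel>.<feature>}.
#' @export
extractFeatures <- function(m, window = c("during", "after"),
                            features = FEATURE_NAMES) {
  stopifnot(all(features %in% FEATURE_NAMES))
  vals <- lapply(m@curves, .curveFeatures, window = window, features = features)
  out <- unlist(vals)
  names(out) <- as.vector(t(outer(names(m@curves), features, paste, sep = ".")))
  out
}

#' Build a feature table from a set of measurements
#'
#' Applies baseline removal (subtract for no correction and for the diff
#' strategy, divide for ratio), optionally the FiO2 correction, then feature
#' extraction, to every measurement.
#'
#' @param measurements list of \linkS4class{ENoseMeasurement}.
#' @param correction \code{"none"}, \code{"diff"} or \code{"ratio"}.
#' @param surfaces named list of \linkS4class{CorrectionSurface} per channel
#'   (required unless \code{correction = "none"}).
#' @param window,features passed to \code{\link{extractFeatures}}.
#' @return A \linkS4class{FeatureTable}.
#' @export
buildFeatureTable <- function(measurements, correction = c("none", "diff", "ratio"),
                              surfaces = NULL, window = c("during", "after"),
                              features = FEATURE_NAMES) {
  correction <- match.arg(correction)
  if (correction != "none" && is.null(surfaces))
    stop("surfaces required for correction '", correction, "'")
  bmode <- if (correction == "ratio") "divide" else "subtract"
  rows <- lapply(measurements, function(m) {
    cm <- m
    cm@curves <- lapply(m@curves, function(cv) {
      b <- removeBaseline(cv, bmode)
      if (correction == "none") b
      else applyCorrection(b, surfaces[[cv@channelId]], m@fio2)
    })
    extractFeatures(cm, window = window, features = features)
  })
  values <- do.call(rbind, rows)
  info <- data.frame(
    animalId = vapply(measurements, function(m) m@animalId, character(1)),
    group = vapply(measurements, function(m) m@group, character(1)),
    timepoint = vapply(measurements, function(m) m@timepoint, character(1)),
    fio2 = vapply(measurements, function(m) m@fio2, numeric(1)))
  rownames(values) <- paste(info$animalId, info$timepoint, sep = ".")
  featureTable(values, info)
}

# ---- IQR outlier screening -------------------------------------------------

#' Compute Tukey-fence screening statistics per (timepoint, feature)
#'
#' For each timepoint and feature column with at least \code{minN} values,
#' computes quartiles, the fences \code{[Q1 - fenceMult*IQR, Q3 +
#' fenceMult*IQR]} and the median of the in-fence values (the imputation
#' value). \code{fenceMult = 0} gives the literal "outside the IQR" rule
#' (fences at the quartiles themselves).
#'
#' @param ft a \linkS4class{FeatureTable} (or data.frame with a
#'   \code{timepoint} column and numeric feature columns).
#' @param fenceMult fence multiplier (default 1.5).
#' @param minN minimum group size to screen (default 4).
#' @return data.frame of statistics, one row per (timepoint, feature).
#' @export
iqrStats <- function(ft, fenceMult = 1.5, minN = 4L) {
  df <- .asFeatureDf(ft)
  featCols <- setdiff(names(df), c("animalId", "group", "timepoint", "fio2"))
  out <- list()
  for (tp in unique(df$timepoint)) {
    sub <- df[df$timepoint == tp, featCols, drop = FALSE]
    for (fc in featCols) {
      v <- sub[[fc]]
      if (length(v) < minN) next
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      lo <- q[1] - fenceMult * iqr; hi <- q[2] + fenceMult * iqr
      keep <- v >= lo & v <= hi
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, feature = fc, q1 = q[1], q3 = q[2],
        lo = lo, hi = hi, impute = stats::median(v[keep]))
    }
  }
  do.call(rbind, out)
}

.asFeatureDf <- function(ft) {
  if (is.data.frame(ft)) return(ft)
  cbind(ft@sampleInfo, as.data.frame(ft@values))
}

.screenOnce <- function(values, info, mask, stats) {
  report <- list()
  if (!is.null(stats) && nrow(stats)) {
    for (i in seq_len(nrow(stats))) {
      st <- stats[i, ]
      rows <- which(info$timepoint == st$timepoint)
      if (!length(rows) || !(st$feature %in% colnames(values))) next
      v <- values[rows, st$feature]
      bad <- v < st$lo | v > st$hi
      if (any(bad)) {
        values[rows[bad], st$feature] <- st$impute
        mask[rows[bad], st$feature] <- TRUE
        report[[length(report) + 1L]] <- data.frame(
          sample = rownames(values)[rows[bad]], timepoint = st$timepoint,
          feature = st$feature, value = v[bad], imputed = st$impute)
      }
    }
  }
  list(values = values, mask = mask,
       report = if (length(report)) do.call(rbind, report) else NULL)
}

#' Screen feature outliers by the IQR rule
#'
#' Masks every cell outside its (timepoint, feature) Tukey fences and imputes
#' it with the in-fence median of that cell group. When statistics are
#' computed from the screened table itself (the default), masking and fence
#' re-estimation are iterated to a fixpoint, so the screen is idempotent:
#' re-screening its own output masks nothing new. With externally supplied
#' \code{stats} (e.g. training-fold statistics applied to a test set) a
#' single pass is made. Rows are never dropped; groups with fewer than
#' \code{minN} values or zero IQR mask nothing (degenerate all-equal groups
#' pass through unchanged).
#'
#' @param ft a \linkS4class{FeatureTable}.
#' @param fenceMult fence multiplier (default 1.5; 0 = literal IQR rule).
#' @param stats optional precomputed \code{\link{iqrStats}} table; default:
#'   computed from \code{ft} itself and iterated.
#' @param minN minimum cell-group size.
#' @param maxIter iteration cap for the fixpoint (default 25).
#' @return list with \code{table} (screened \linkS4class{FeatureTable}),
#'   \code{report} (data.frame of masked cells) and \code{stats} (the
#'   final fence statistics).
#' @export
iqrScreen <- function(ft, fenceMult = 1.5, stats = NULL, minN = 4L,
                      maxIter = 25L) {
  values <- ft@values; mask <- ft@mask
  reports <- list()
  if (!is.null(stats)) {
    out <- .screenOnce(values, ft@sampleInfo, mask, stats)
    values <- out$values; mask <- out$mask
    reports <- list(out$report)
  } else {
    for (it in seq_len(maxIter)) {
      cur <- featureTable(values, ft@sampleInfo, mask)
      stats <- iqrStats(cur, fenceMult = fenceMult, minN = minN)
      out <- .screenOnce(values, ft@sampleInfo, mask, stats)
      if (is.null(out$report)) break
      values <- out$values; mask <- out$mask
      reports[[length(reports) + 1L]] <- out$report
    }
  }
  report <- if (length(reports) && !all(vapply(reports, is.null, TRUE)))
    do.call(rbind, reports)
  else data.frame(sample = character(), timepoint = character(),
                  feature = character(), value = numeric(), imputed = numeric())
  list(table = featureTable(values, ft@sampleInfo, mask),
       report = report, stats = stats)
}
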