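# Ventilator-synchronized breath sampling: pressure-trace simulation,
# threshold exhalation detection, and bag-fill accounting.

#' Simulate an expiratory-line pressure trace
#'
#' Square-wave-like pressure-control waveform: pressure sits at PIP during
#' inspiration and at PEEP during expiration, with optional additive Gaussian
#' noise. Used to exercise the exhalation detector without hardware.
#'
#' @param rateBpm breathing rate, breaths per minute (> 0).
#' @param inspFrac inspiratory fraction of the cycle, in (0, 1).
#' @param pip peak inspiratory pressure, cmH2O (> peep).
#' @param peep positive end-expiratory pressure, cmH2O (>= 0).
#' @param durationS trace duration, seconds (> 0).
#' @param noiseSd additive Gaussian noise SD, cmH2O.
#' @param seed integer seed; the trace is reproducible per seed.
#' @param sampleRateHz sampling rate of the trace, Hz (default 10).
#' @param threshold detection threshold stored with the trace; default midway
#'   between PEEP and PIP.
#' @return A \linkS4class{PressureTrace}.
#' @export
simulatePressureTrace <- function(rateBpm, inspFrac, pip, peep, durationS,
                                  noiseSd = 0, seed = 1L, sampleRateHz = 10,
                                  threshold = (pip + peep) / 2) {
  if (durationS <= 0 || rateBpm <= 0) stop("duration and rate must be positive")
  if (!(pip > peep && peep >= 0)) stop("require pip > peep >= 0")
  if (!(inspFrac > 0 && inspFrac < 1)) stop("inspFrac must lie in (0, 1)")
  n <- round(durationS * sampleRateHz)
  t <- (seq_len(n) - 1L) / sampleRateHz
  period <- 60 / rateBpm
  phase <- (t %% period) / period
  p <- ifelse(phase < inspFrac, pip, peep)
  if (noiseSd > 0) {
    p <- p + withr::with_seed(as.integer(seed), stats::rnorm(n, 0, noiseSd))
  }
  pressureTrace(t, p, threshold)
}

#' Detect exhalation segments from a pressure trace
#'
#' A segment opens at the first sample strictly below the threshold that
#' follows a sample at or above it (exhalation = pressure drop below the
#' user-set threshold) and closes at the next sample at or above the
#' threshold. An optional debounce requires \code{debounce} consecutive
#' samples on the new side of the threshold before a crossing is accepted;
#' the segment boundary is still the first sample of the accepted run. A
#' segment still open at the end of the trace is closed at the last sample
#' and flagged truncated.
#'
#' @param p a \linkS4class{PressureTrace}.
#' @param debounce consecutive-sample debounce count (default 2; 1 disables).
#' @return data.frame with columns \code{start_s}, \code{end_s},
#'   \code{truncated}; zero rows if the threshold is never crossed downward.
#' @export
detectExhalations <- function(p, debounce = 2L) {
  validObject(p)
  thr <- p@threshold
  below <- p@pressure < thr
  n <- length(below)
  runOk <- function(i, state) {
    # samples i .. i+debounce-1 (truncated at trace end) all on the new side
    j <- seq.int(i, min(n, i + debounce - 1L))
    all(below[j] == state)
  }
  starts <- numeric(0); ends <- numeric(0); trunc <- logical(0)
  inSeg <- FALSE
  i <- 2L
  segStart <- NA_real_
  while (i <= n) {
    if (!inSeg) {
      if (below[i] && !below[i - 1L] && runOk(i, TRUE)) {
        inSeg <- TRUE
        segStart <- p@times[i]
      }
    } else {
      if (!below[i] && runOk(i, FALSE)) {
        starts <- c(starts, segStart); ends <- c(ends, p@times[i])
        trunc <- c(trunc, FALSE)
        inSeg <- FALSE
      }
    }
    i <- i + 1L
  }
  if (inSeg) {
    starts <- c(starts, segStart); ends <- c(ends, p@times[n])
    trunc <- c(trunc, TRUE)
  }
  data.frame(start_s = starts, end_s = ends, truncated = trunc)
}

#' Bag-fill accounting for breath collection
#'
#' The operator chooses how many breathing acts fill the bag; collection uses
#' exhalation segments only. With tidal volume v and bag volume V,
#' \code{ceiling(V / v)} breaths are needed.
#'
#' @param segments data.frame of exhalation segments (\code{\link{detectExhalations}}).
#' @param tidalVolumeL exhaled volume per breath, liters (> 0).
#' @param bagVolumeL bag volume, liters (> 0); the study bags hold 6 L.
#' @return list with \code{nBreathsUsed} and logical \code{filled}.
#' @export
fillBag <- function(segments, tidalVolumeL, bagVolumeL = 6) {
  if (tidalVolumeL <= 0 || bagVolumeL <= 0) stop("volumes must be positive")
  needed <- ceiling(bagVolumeL / tidalVolumeL)
  avail <- nrow(segments)
  if (avail >= needed) list(nBreathsUsed = as.integer(needed), filled = TRUE)
  else list(nBreathsUsed = as.integer(avail), filled = FALSE)
}
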