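## Rotary-encoder processing: speed traces, run-bout detection and
## bout-aligned fluorescence metrics.

#' Convert an encoder stream to a binned speed trace
#'
#' Speed per bin = (state changes in bin x mm per change) / bin width,
#' reported in cm/s. The published criterion's geometry (2.0 mm per state
#' change) makes 65 changes equal 13 cm.
#'
#' @param stream an \linkS4class{EncoderStream}.
#' @param binWidth bin width, s (default 0.1).
#' @return a \linkS4class{FluorescenceTrace} holding speed in cm/s.
#' @export
encoderToSpeed <- function(stream, binWidth = 0.1) {
  stopifnot(is(stream, "EncoderStream"))
  nbins <- max(1L, floor(stream@duration / binWidth + 1e-9))
  ev <- eventTimes(stream)
  counts <- tabulate(pmin(floor(ev / binWidth) + 1L, nbins), nbins)
  speed <- counts * stream@mmPerChange / 10 / binWidth   # cm/s
  FluorescenceTrace(speed, samplingRate = 1 / binWidth, t0 = 0)
}

#' Detect spontaneous running-bout onsets
#'
#' A bout onset is the first state change following a 1-s quiescent window
#' containing at most one change, provided the 5 s starting at that change
#' contain at least 65 changes (13 cm at 2.0 mm per change). Candidates are
#' evaluated on the raw event times; after a detected onset, detection is
#' suppressed for the bout-counting window so a single run is not counted
#' twice.
#'
#' @param stream an \linkS4class{EncoderStream}.
#' @param minChanges minimum state changes in the counting window
#'   (default 65).
#' @param countWindow counting window after onset, s (default 5).
#' @param quietWindow quiescence window before onset, s (default 1).
#' @param maxQuietChanges maximum changes tolerated in the quiescence
#'   window (default 1).
#' @return numeric vector of bout-onset times, s.
#' @export
detectRunBouts <- function(stream, minChanges = 65, countWindow = 5,
                           quietWindow = 1, maxQuietChanges = 1) {
  stopifnot(is(stream, "EncoderStream"))
  ev <- eventTimes(stream)
  onsets <- numeric(0)
  lastEnd <- -Inf
  for (i in seq_along(ev)) {
    t <- ev[i]
    if (t < lastEnd) next
    nQuiet <- sum(ev >= t - quietWindow & ev < t)
    if (nQuiet > maxQuietChanges) next
    nCount <- sum(ev >= t & ev < t + countWindow)
    if (nCount >= minChanges) {
      onsets <- c(onsets, t)
      lastEnd <- t + countWindow
    }
  }
  onsets
}

#' Peak speed and peak fluorescence around bout onsets
#'
#' For each bout onset, takes the maximum running speed and the maximum
#' z-scored fluorescence in the window 2.5-5 s after onset (the published
#' post-onset metric window), along with the times of those maxima. The
#' fluorescence trace is expected z-scored but not detrended.
#'
#' @param onsets numeric vector of bout onsets, s.
#' @param speedTrace speed trace from \code{\link{encoderToSpeed}}.
#' @param zTrace z-scored fluorescence trace (any
#'   \linkS4class{FluorescenceTrace}).
#' @param metricWindow numeric length-2: window after onset, s
#'   (default c(2.5, 5)).
#' @return data.frame with columns \code{onset}, \code{peakSpeed},
#'   \code{peakSpeedTime}, \code{peakZ}, \code{peakZTime}; bouts without
#'   full trace coverage are skipped with a warning.
#' @export
boutMetrics <- function(onsets, speedTrace, zTrace,
                        metricWindow = c(2.5, 5)) {
  stopifnot(is(speedTrace, "FluorescenceTrace"),
            is(zTrace, "FluorescenceTrace"))
  out <- data.frame(onset = numeric(0), peakSpeed = numeric(0),
                    peakSpeedTime = numeric(0), peakZ = numeric(0),
                    peakZTime = numeric(0))
  ts <- traceTimes(speedTrace); vs <- traceValues(speedTrace)
  tz <- traceTimes(zTrace); vz <- traceValues(zTrace)
  for (o in onsets) {
    lo <- o + metricWindow[1]; hi <- o + metricWindow[2]
    si <- which(ts >= lo & ts <= hi)
    zi <- which(tz >= lo & tz <= hi)
    if (length(si) == 0 || length(zi) == 0 ||
        hi > min(max(ts), max(tz)) + 1e-9) {
      warning("bout at ", o, " s skipped: traces do not cover onset + ",
              metricWindow[2], " s")
      next
    }
    ips <- si[which.max(vs[si])]
    ipz <- zi[which.max(vz[zi])]
    out <- rbind(out, data.frame(onset = o, peakSpeed = vs[ips],
                                 peakSpeedTime = ts[ips], peakZ = vz[ipz],
                                 peakZTime = tz[ipz]))
  }
  out
}

#' Regress bout fluorescence peaks on speed peaks
#'
#' Ordinary least squares of peak z-scored fluorescence on peak running
#' speed across bouts, with the F test of the regression (the published
#' bout-amplitude analysis).
#'
#' @param bouts data.frame from \code{\link{boutMetrics}} (needs columns
#'   \code{peakSpeed}, \code{peakZ}).
#' @return list with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{F}, \code{p}, \code{n}.
#' @export
correlateBoutPeaks <- function(bouts) {
  if (nrow(bouts) < 3) stop("at least 3 bouts are required")
  fit <- stats::lm(peakZ ~ peakSpeed, data = bouts)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = sm$r.squared, F = unname(fstat[1]),
       p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                            lower.tail = FALSE)),
       n = nrow(bouts))
}
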