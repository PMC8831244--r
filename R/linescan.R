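## Sensor activation kinetics from dual-channel 550-Hz line scans with
## red-dye arrival gating.

#' Classify line-scan pixels as membrane or cytosol
#'
#' A pixel belongs to the membrane when its fractional green-channel change
#' between a pre-ligand and a post-ligand window exceeds the threshold:
#' (mean_post - mean_pre) / mean_pre > thresholdFrac. Pixels with
#' non-positive pre-ligand mean are flagged "invalid".
#'
#' @param rec a \linkS4class{LineScanRecording}.
#' @param preWindow,postWindow numeric length-2 (start, end) windows, s.
#' @param thresholdFrac fractional-change threshold (default 0.5).
#' @return a \linkS4class{PixelClassMap}.
#' @export
classifyMembranePixels <- function(rec, preWindow, postWindow,
                                   thresholdFrac = 0.5) {
  stopifnot(is(rec, "LineScanRecording"))
  n <- ncol(rec@green)
  t <- (seq_len(n) - 1) / rec@samplingRate
  pre <- which(t >= preWindow[1] & t < preWindow[2])
  post <- which(t >= postWindow[1] & t < postWindow[2])
  if (!length(pre) || !length(post))
    stop("pre/post windows must lie within the recording")
  mPre <- rowMeans(rec@green[, pre, drop = FALSE])
  mPost <- rowMeans(rec@green[, post, drop = FALSE])
  cls <- ifelse(mPre <= 0, "invalid",
                ifelse((mPost - mPre) / mPre > thresholdFrac,
                       "membrane", "cytosol"))
  new("PixelClassMap", classes = cls, thresholdUsed = thresholdFrac)
}

#' Red-dye arrival latency of a line-scan trial
#'
#' Latency is the time from the last baseline-level sample to the first
#' sample reaching 85\% of the maximal red-channel change, with baseline
#' taken as the mean of the first 100 ms. Trials with latency of 50 ms or
#' more (slow solution exchange) are rejected for kinetics.
#'
#' @param red numeric vector, the red-channel trace (for a recording, the
#'   pixel-averaged red channel).
#' @param rateHz sampling rate, Hz.
#' @param baselineS baseline duration at the start of the trace, s.
#' @param maxLatency acceptance bound, s (default 0.05).
#' @return list with \code{latency} (s; NA when the channel never rises),
#'   \code{onsetTime} (time of the last baseline-level sample, s) and
#'   \code{accepted}.
#' @export
dyeOnsetLatency <- function(red, rateHz, baselineS = 0.1,
                            maxLatency = 0.05) {
  red <- as.numeric(red)
  n <- length(red)
  t <- (seq_len(n) - 1) / rateHz
  base <- mean(red[t < baselineS])
  mx <- max(red)
  if (mx <= base)
    return(list(latency = NA_real_, onsetTime = NA_real_,
                accepted = FALSE))
  thr <- base + 0.85 * (mx - base)
  i85 <- which(red >= thr)[1]
  below <- which(red[seq_len(i85 - 1)] <= base)
  i0 <- if (length(below)) max(below) else 1L
  lat <- t[i85] - t[i0]
  list(latency = lat, onsetTime = t[i0], accepted = lat < maxLatency)
}

#' Fit membrane-pixel activation time constants
#'
#' Applies the red-dye arrival gate, low-pass filters each membrane pixel's
#' green trace (zero-phase 4th-order Butterworth) and fits a one-phase
#' exponential association from the dye arrival to the end of the
#' recording. The summary time constant is the mean over converged fits.
#'
#' @param rec a \linkS4class{LineScanRecording}.
#' @param classmap a \linkS4class{PixelClassMap} for the recording.
#' @param lowpassCutoff low-pass cutoff, Hz (default 20).
#' @param maxLatency dye-gate acceptance bound, s.
#' @param enforceGate reject the trial (error) when the dye gate fails
#'   (default TRUE).
#' @param fitDelay dead time after dye arrival excluded from the fit, s
#'   (default 0.05); it skips the low-pass filter's transition band around
#'   the response onset, which would otherwise bias tau. The exponential
#'   time constant is unaffected by a shifted fit origin.
#' @return list with \code{fits} (list of \linkS4class{KineticsFit}),
#'   \code{tauMean} (s), \code{latency} and \code{gatePassed}.
#' @export
fitPixelTaus <- function(rec, classmap, lowpassCutoff = 20,
                         maxLatency = 0.05, enforceGate = TRUE,
                         fitDelay = 0.05) {
  stopifnot(is(rec, "LineScanRecording"), is(classmap, "PixelClassMap"))
  mem <- which(classmap@classes == "membrane")
  if (!length(mem)) stop("no membrane pixels in the classification")
  sr <- rec@samplingRate
  gate <- dyeOnsetLatency(colMeans(rec@red), sr, maxLatency = maxLatency)
  if (!gate$accepted && enforceGate)
    stop("trial rejected: red-dye latency ",
         format(gate$latency), " s (gate < ", maxLatency, " s)")
  bf <- signal::butter(4, lowpassCutoff / (sr / 2), type = "low")
  n <- ncol(rec@green)
  t <- (seq_len(n) - 1) / sr
  from <- if (is.finite(gate$onsetTime)) gate$onsetTime else 0
  idx <- which(t >= from + fitDelay)
  # reflective padding suppresses the zero-phase filter's edge transients
  pad <- min(n - 1L, ceiling(sr / lowpassCutoff) * 4L)
  fits <- lapply(mem, function(p) {
    v <- rec@green[p, ]
    vp <- c(2 * v[1] - rev(v[2:(pad + 1)]), v,
            2 * v[n] - rev(v[(n - pad):(n - 1)]))
    y <- as.numeric(signal::filtfilt(bf, vp))[(pad + 1):(pad + n)]
    fitExpAssociation(y[idx], "rise", rateHz = sr)
  })
  taus <- vapply(fits, function(f)
    if (isConverged(f)) f@tau else NA_real_, numeric(1))
  list(fits = fits, tauMean = mean(taus, na.rm = TRUE),
       latency = gate$latency, gatePassed = gate$accepted)
}
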