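## Seeded generators for every supported input modality, with ground truth
## recorded in the object metadata. Identical (seed, parameters) always
## yield identical output; generation never disturbs the caller's RNG state.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a substream seed from a global seed
#'
#' One global integer seed drives all generators in a pipeline run; each
#' data stream uses \code{splitSeed(seed, index)} with a documented fixed
#' index per stream so streams are independent yet reproducible. The result
#' always stays below 2^31.
#'
#' @param seed global integer seed.
#' @param index non-negative integer substream index.
#' @return an integer seed.
#' @export
splitSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %%
             .Machine$integer.max)
}

#' Generate a synthetic fiber-photometry trace
#'
#' Baseline + linear drift + stimulus-locked sensor responses + Gaussian
#' noise, sampled at 400 Hz. During each train the response follows
#' amplitude (1 - exp(-t/tauRise)); after train offset it decays as
#' exp(-t/tauDecay) from the value reached at offset. Train intervals are
#' recorded as annotations and all ground-truth parameters in the metadata.
#'
#' @param seed integer seed.
#' @param duration recording duration, s.
#' @param rateHz sampling rate, Hz (photometry hardware samples at 400 Hz).
#' @param baseline baseline fluorescence, arbitrary units.
#' @param drift linear drift slope, units/s (anesthesia slowly bleaches the
#'   baseline, hence a small negative default).
#' @param trains list of \linkS4class{StimTrain} (or a single one).
#' @param amplitude peak response amplitude per train, units; recycled.
#' @param tauRise,tauDecay response time constants, s (defaults are the
#'   published 20 Hz in vivo estimates, 6.77 s and 16.31 s).
#' @param noiseSd Gaussian noise s.d., units (default 10\% of the first
#'   amplitude).
#' @return a \linkS4class{FluorescenceTrace} with \code{metadata$groundTruth}.
#' @export
genPhotometry <- function(seed, duration = 180, rateHz = 400,
                          baseline = 100, drift = -0.05,
                          trains = list(StimTrain(onset = 60)),
                          amplitude = 10, tauRise = 6.77, tauDecay = 16.31,
                          noiseSd = 0.1 * amplitude[1]) {
  if (is(trains, "StimTrain")) trains <- list(trains)
  if (any(c(tauRise, tauDecay) <= 0)) stop("time constants must be positive")
  n <- round(duration * rateHz)
  t <- (seq_len(n) - 1) / rateHz
  amplitude <- rep_len(amplitude, length(trains))
  resp <- numeric(n)
  ann <- data.frame(label = character(0), start = numeric(0),
                    end = numeric(0))
  for (k in seq_along(trains)) {
    tr <- trains[[k]]
    on <- tr@onset; off <- tr@onset + tr@duration
    rise <- t >= on & t < off
    resp[rise] <- resp[rise] +
      amplitude[k] * (1 - exp(-(t[rise] - on) / tauRise))
    peak <- amplitude[k] * (1 - exp(-tr@duration / tauRise))
    post <- t >= off
    resp[post] <- resp[post] + peak * exp(-(t[post] - off) / tauDecay)
    ann <- rbind(ann, data.frame(label = "stim", start = on,
                                 end = min(off, duration)))
  }
  noise <- .withSeed(seed, stats::rnorm(n, 0, noiseSd))
  FluorescenceTrace(baseline + drift * t + resp + noise,
    samplingRate = rateHz, t0 = 0, annotations = ann,
    metadata = list(seed = seed, groundTruth = list(
      baseline = baseline, drift = drift, amplitude = amplitude,
      tauRise = tauRise, tauDecay = tauDecay, noiseSd = noiseSd,
      trains = trains)))
}

#' Generate a synthetic rotary-encoder stream
#'
#' Sparse Poisson background events during quiescence (well under the
#' one-change-per-second bout-detection gate) and dense event trains during
#' scheduled running bouts: each bout contains exactly
#' \code{round(rate * duration)} changes at uniformly jittered times, so a
#' schedule determines whether the bout criterion is met. A guard interval
#' of 4 s before each bout onset is kept free of background events so the
#' scheduled bouts satisfy the quiescence criterion by construction and
#' stray pre-onset events cannot advance the detected onset; the first
#' in-bout event falls exactly at the scheduled onset.
#'
#' @param seed integer seed.
#' @param duration recording duration, s.
#' @param bouts data.frame with columns \code{onset}, \code{duration} (s)
#'   and \code{rate} (state changes per second during the bout); bouts must
#'   not overlap. An empty data.frame gives quiescence only.
#' @param quiescentRate background event rate, changes/s (default 0.2).
#' @param mmPerChange distance per state change, mm.
#' @return an \linkS4class{EncoderStream}.
#' @export
genEncoder <- function(seed, duration = 120,
                       bouts = data.frame(onset = numeric(0),
                                          duration = numeric(0),
                                          rate = numeric(0)),
                       quiescentRate = 0.2, mmPerChange = 2.0) {
  if (nrow(bouts) > 1) {
    o <- order(bouts$onset)
    bouts <- bouts[o, , drop = FALSE]
    if (any(utils::head(bouts$onset + bouts$duration, -1) >
            utils::tail(bouts$onset, -1)))
      stop("bouts must not overlap")
  }
  ev <- .withSeed(seed, {
    nq <- stats::rpois(1, quiescentRate * duration)
    quiet <- sort(stats::runif(nq, 0, duration))
    inb <- unlist(lapply(seq_len(nrow(bouts)), function(k) {
      b <- bouts[k, ]
      nn <- max(0L, round(b$rate * b$duration) - 1L)
      c(b$onset, b$onset + sort(stats::runif(nn, 0, b$duration)))
    }))
    # keep background events clear of a 4-s pre-onset guard and of bouts
    for (k in seq_len(nrow(bouts))) {
      b <- bouts[k, ]
      quiet <- quiet[quiet < b$onset - 4 | quiet > b$onset + b$duration]
    }
    sort(c(quiet, inb))
  })
  ev <- ev[ev >= 0 & ev <= duration]
  EncoderStream(ev, duration = duration, mmPerChange = mmPerChange)
}

## Shared latent activity course for hotspot movies: a train of square
## release transients (~2 s long, one per ~6 s, jittered) whose amplitude
## follows a Gaussian envelope centred in the post-anesthesia period. The
## ~1/3 duty cycle matters: the binarization marks pixels whose value
## exceeds their temporal median + s.d., so hotspot pixels must be "on"
## clearly more often than the ~16% noise-driven rate of background pixels
## yet less than half the time (or the median itself shifts up).
.latentCourse <- function(nFrames, frameRate, centerS, widthS,
                          burstEvery = 6, burstDur = c(1.5, 2.5)) {
  t <- (seq_len(nFrames) - 1) / frameRate
  dur <- max(t)
  sched <- seq(0, dur, by = burstEvery)
  centers <- sched + stats::runif(length(sched), -1.5, 1.5)
  lens <- stats::runif(length(sched), burstDur[1], burstDur[2])
  amps <- stats::runif(length(sched), 0.6, 1) *
    exp(-0.5 * ((centers - centerS) / widthS)^2)
  lat <- numeric(nFrames)
  for (j in seq_along(centers)) {
    on <- abs(t - centers[j]) < lens[j] / 2
    lat[on] <- pmax(lat[on], amps[j])
  }
  lat
}

#' Generate a synthetic two-photon movie
#'
#' Emulates a cortical sensor recording during emergence from anesthesia:
#' a uniform background, a global sigmoidal wake ramp beginning about one
#' minute after anesthesia switch-off, a set of circular hotspots sharing a
#' single latent activity time course (strongest in minutes 3-5, so the
#' most-active-minute selector has a true optimum), Poisson-like noise
#' (Gaussian with variance proportional to the mean) and optional dark
#' vertical blood-vessel stripes.
#'
#' @param seed integer seed.
#' @param width,height frame size in pixels.
#' @param frameRate frames per second (published range 4.9-7.5).
#' @param duration movie duration, s (must cover the search period).
#' @param background baseline intensity, arbitrary units.
#' @param nHotspots number of hotspots (0 gives a control movie, the
#'   analogue of a binding-dead sensor).
#' @param hotspotRadius hotspot radius, px.
#' @param hotspotAmplitude peak added intensity in hotspots, units.
#' @param rampAmplitude fractional global fluorescence increase on waking
#'   (the ground truth for the first-vs-last-minute dF/F0 difference).
#' @param noiseScale noise s.d. = noiseScale * sqrt(mean intensity).
#' @param nVessels number of dark vertical vessel stripes.
#' @param vesselWidth stripe width, px.
#' @param anesthesiaOffS time of anesthesia switch-off, s.
#' @return an \linkS4class{ImagingMovie}; \code{movieMetadata(x)$groundTruth}
#'   holds hotspot centers, the hotspot mask, the latent course and the ramp.
#' @export
genMovie <- function(seed, width = 128, height = 128, frameRate = 4.9,
                     duration = 420, background = 100, nHotspots = 12,
                     hotspotRadius = 9, hotspotAmplitude = 60,
                     rampAmplitude = 0.5, noiseScale = 1, nVessels = 2,
                     vesselWidth = 3, anesthesiaOffS = 60) {
  if (nHotspots > 0 && hotspotRadius <= 0)
    stop("'hotspotRadius' must be positive")
  nFrames <- round(duration * frameRate)
  t <- (seq_len(nFrames) - 1) / frameRate
  .withSeed(seed, {
    # hotspot centers, kept inside the frame and apart from each other
    centers <- matrix(numeric(0), 0, 2)
    guard <- hotspotRadius + 2
    tries <- 0
    while (nrow(centers) < nHotspots && tries < 50000) {
      cand <- c(stats::runif(1, guard, height - guard),
                stats::runif(1, guard, width - guard))
      # hotspots may touch but not coincide (subregions can abut in vivo)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > 1.5 * hotspotRadius)
        centers <- rbind(centers, cand)
      tries <- tries + 1
    }
    if (nrow(centers) < nHotspots)
      stop("could not place ", nHotspots, " non-overlapping hotspots")
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    mask <- matrix(0, height, width)
    for (k in seq_len(nrow(centers)))
      mask[(rows - centers[k, 1])^2 + (cols - centers[k, 2])^2 <=
             hotspotRadius^2] <- 1
    vessel <- matrix(FALSE, height, width)
    if (nVessels > 0) {
      starts <- sort(sample.int(width - vesselWidth, nVessels))
      for (s in starts) vessel[, s:(s + vesselWidth - 1)] <- TRUE
    }
    # global wake ramp: sigmoid starting ~1 min after anesthesia off
    ramp <- rampAmplitude / (1 + exp(-(t - (anesthesiaOffS + 90)) / 20))
    # hotspot activity peaks after the global ramp has plateaued
    latent <- .latentCourse(nFrames, frameRate,
                            centerS = anesthesiaOffS + 240, widthS = 60)
    frames <- array(0, c(nFrames, height, width))
    for (i in seq_len(nFrames)) {
      mu <- background * (1 + ramp[i]) +
        hotspotAmplitude * latent[i] * mask
      mu[vessel] <- 1
      frames[i, , ] <- pmax(mu + stats::rnorm(height * width) *
                              noiseScale * sqrt(mu), 0)
    }
    ImagingMovie(frames, frameRate = frameRate, pixelSize = 1.27,
      anesthesiaOffFrame = max(1, round(anesthesiaOffS * frameRate)),
      metadata = list(seed = seed, groundTruth = list(
        hotspotCenters = centers, hotspotRadius = hotspotRadius,
        hotspotMask = mask, vesselMask = vessel, latent = latent,
        rampAmplitude = rampAmplitude, background = background,
        hotspotAmplitude = hotspotAmplitude)))
  })
}

#' Generate a synthetic dual-channel line-scan recording
#'
#' Membrane pixels of the green (sensor) channel rise mono-exponentially
#' with time constant \code{tau} after the ligand arrives; cytosol pixels
#' stay flat. The red (dye) channel steps up at the arrival time with a
#' configurable linear ramp, providing the arrival-latency gate.
#'
#' @param seed integer seed.
#' @param nPixels pixels along the scanned line.
#' @param membraneFrac fraction of pixels on the membrane.
#' @param duration recording duration, s.
#' @param rateHz line rate, Hz (hardware uses 550).
#' @param arrivalTime ligand/dye arrival, s.
#' @param tau sensor activation time constant, s (default the published
#'   0.596 s mean for orexin-A).
#' @param baseline green baseline, units.
#' @param responseAmp green response amplitude, units (default a 9-fold
#'   rise over baseline, matching the sensor's dynamic range).
#' @param noiseFrac Gaussian noise s.d. as a fraction of
#'   \code{responseAmp}.
#' @param redRampMs red-channel 0-to-max rise time, ms.
#' @return a \linkS4class{LineScanRecording} with ground truth in metadata.
#' @export
genLinescan <- function(seed, nPixels = 32, membraneFrac = 0.5,
                        duration = 5, rateHz = 550, arrivalTime = 1,
                        tau = 0.596, baseline = 50,
                        responseAmp = 9 * baseline, noiseFrac = 0.1,
                        redRampMs = 10) {
  if (arrivalTime >= duration) stop("arrival time beyond the recording")
  n <- round(duration * rateHz)
  t <- (seq_len(n) - 1) / rateHz
  .withSeed(seed, {
    nMem <- round(nPixels * membraneFrac)
    classes <- rep("cytosol", nPixels)
    if (nMem > 0) classes[sample.int(nPixels, nMem)] <- "membrane"
    riseT <- pmax(t - arrivalTime, 0)
    memCourse <- responseAmp * (1 - exp(-riseT / tau)) * (t >= arrivalTime)
    green <- matrix(baseline, nPixels, n)
    if (nMem > 0)
      green[classes == "membrane", ] <-
        green[classes == "membrane", , drop = FALSE] +
        matrix(memCourse, nMem, n, byrow = TRUE)
    green <- green + matrix(stats::rnorm(nPixels * n, 0,
                                         noiseFrac * responseAmp),
                            nPixels, n)
    redCourse <- 10 + 90 * pmin(riseT / (redRampMs / 1000), 1)
    red <- matrix(redCourse, nPixels, n, byrow = TRUE) +
      matrix(stats::rnorm(nPixels * n, 0, 1), nPixels, n)
    LineScanRecording(green, red, samplingRate = rateHz,
      ligandLabel = "orexin-A",
      metadata = list(seed = seed, groundTruth = list(
        classes = classes, tau = tau, arrivalTime = arrivalTime,
        baseline = baseline, responseAmp = responseAmp,
        noiseFrac = noiseFrac, redRampMs = redRampMs)))
  })
}

#' Generate a synthetic dose-response titration
#'
#' Responses follow the four-parameter logistic with multiplicative
#' Gaussian noise; doses are log-spaced around the ground-truth EC50.
#'
#' @param seed integer seed.
#' @param ec50 ground-truth EC50, mol/L (default the published 75 nM
#'   orexin-A affinity in HEK cells).
#' @param hill Hill slope.
#' @param top,bottom response asymptotes.
#' @param nDoses number of doses.
#' @param decades dose range in log10 units, centred on \code{ec50}.
#' @param noiseFrac multiplicative noise fraction.
#' @return list with \code{doses}, \code{responses}, \code{groundTruth}.
#' @export
genDoseResponse <- function(seed, ec50 = 75e-9, hill = 1, top = 1,
                            bottom = 0, nDoses = 8, decades = 4,
                            noiseFrac = 0.1) {
  if (nDoses < 4) stop("at least 4 doses are required")
  doses <- ec50 * 10^seq(-decades / 2, decades / 2, length.out = nDoses)
  ytrue <- bottom + (top - bottom) / (1 + (ec50 / doses)^hill)
  y <- .withSeed(seed, ytrue * (1 + stats::rnorm(nDoses, 0, noiseFrac)))
  list(doses = doses, responses = y,
       groundTruth = list(ec50 = ec50, hill = hill, top = top,
                          bottom = bottom, noiseFrac = noiseFrac))
}

#' Generate a synthetic hypnogram with a paired state-modulated dF/F0 trace
#'
#' A semi-Markov vigilance-state sequence (wake -> NREM -> {REM | wake},
#' REM -> wake) with exponential dwell times, and a paired dF/F0 trace that
#' is offset per state: wake and NREM sit at a common high level and REM at
#' a level lower by \code{remDrop}, mirroring the observed rapid signal
#' drop at REM onset and recovery at REM offset.
#'
#' @param seed integer seed.
#' @param nEpochs number of 1-s epochs.
#' @param meanDwell named numeric, mean dwell per state in seconds.
#' @param minDwell minimum dwell, s (kept >= 16 so transitions are
#'   analysable with the +/-15 s window).
#' @param remDrop drop of dF/F0 during REM (ground truth for transition
#'   deltas).
#' @param level dF/F0 level in wake/NREM.
#' @param rateHz sampling rate of the paired trace, Hz.
#' @param noiseSd Gaussian noise s.d. on the trace.
#' @param states optional explicit state sequence (overrides simulation;
#'   dwell parameters ignored).
#' @return list with \code{hypnogram} (\linkS4class{Hypnogram}) and
#'   \code{trace} (\linkS4class{DffTrace}).
#' @export
genHypnogram <- function(seed, nEpochs = 1800,
                         meanDwell = c(wake = 120, NREM = 180, REM = 60),
                         minDwell = 20, remDrop = 0.2, level = 0.2,
                         rateHz = 10, noiseSd = 0.01, states = NULL) {
  if (is.null(states)) {
    states <- .withSeed(seed, {
      out <- character(0)
      cur <- "wake"
      while (length(out) < nEpochs) {
        dwell <- max(minDwell, round(stats::rexp(1, 1 / meanDwell[[cur]])))
        out <- c(out, rep(cur, dwell))
        cur <- switch(cur,
          wake = "NREM",
          NREM = if (stats::runif(1) < 0.4) "REM" else "wake",
          REM = "wake")
      }
      out[seq_len(nEpochs)]
    })
  } else {
    if (!all(states %in% c("wake", "NREM", "REM")))
      stop("invalid state name in 'states'")
    nEpochs <- length(states)
  }
  hyp <- Hypnogram(states, epochLength = 1)
  n <- round(nEpochs * rateHz)
  epoch <- pmin(floor((seq_len(n) - 1) / rateHz) + 1, nEpochs)
  lev <- ifelse(states[epoch] == "REM", level - remDrop, level)
  noise <- .withSeed(splitSeed(seed, 1), stats::rnorm(n, 0, noiseSd))
  dff <- new("DffTrace", values = lev + noise, samplingRate = rateHz,
             t0 = 0,
             annotations = data.frame(label = character(0),
                                      start = numeric(0), end = numeric(0)),
             metadata = list(seed = seed, groundTruth = list(
               remDrop = remDrop, level = level, noiseSd = noiseSd)),
             baselineValue = 1, baselineWindow = c(0, nEpochs))
  list(hypnogram = hyp, trace = dff)
}
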