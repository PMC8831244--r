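## Trial- and event-level fiber-photometry analysis: optogenetic stimulation
## trials, behavioural event comparisons and sleep-state transition deltas.

#' Analyze one optogenetic stimulation trial
#'
#' Runs the full published trial pipeline on a raw 400-Hz photometry trace:
#' extract a window from 30 s before to 90 s after train onset, average into
#' 100-ms bins, Savitzky-Golay filter, remove the linear trend anchored on
#' the medians of the first and last 30 s of the window, z-score against the
#' 10-s pre-stimulus baseline, then (i) take the peak z during the laser-on
#' period, (ii) fit a one-phase exponential association on the 10 s
#' following onset (after a 4-s Savitzky-Golay pass on that window) and
#' (iii) fit a one-phase exponential decay from train offset to the
#' post-offset minimum. Trials whose fits fall below the quality threshold
#' are flagged excluded, mirroring the published poor-fit exclusion.
#'
#' @param trace raw \linkS4class{FluorescenceTrace} covering the window.
#' @param stim a \linkS4class{StimTrain}.
#' @param windowPre,windowPost window extent before/after train onset, s.
#' @param binWidth bin width, s.
#' @param sgWindow Savitzky-Golay window, s.
#' @param riseWindow duration after onset used for the rise fit, s.
#' @param minR2 exclusion threshold on fit R^2 (default 0.5).
#' @param smoothDecay also smooth the decay window before fitting (default
#'   TRUE, matching the "smoothed and fitted as above" decay treatment).
#' @return a \linkS4class{StimResponse}.
#' @export
analyzeStimTrial <- function(trace, stim, windowPre = 30, windowPost = 90,
                             binWidth = 0.1, sgWindow = 4, riseWindow = 10,
                             minR2 = 0.5, smoothDecay = TRUE) {
  stopifnot(is(trace, "FluorescenceTrace"), is(stim, "StimTrain"))
  on <- stim@onset; off <- stim@onset + stim@duration
  tt <- traceTimes(trace)
  if (on - windowPre < tt[1] - 1e-9 ||
      on + windowPost > tt[length(tt)] + 1e-9)
    stop("trace does not cover [onset - ", windowPre, ", onset + ",
         windowPost, "] s")
  keep <- which(tt >= on - windowPre & tt < on + windowPost)
  win <- FluorescenceTrace(traceValues(trace)[keep],
                           samplingRate = samplingRate(trace),
                           t0 = tt[keep[1]])
  binned <- binTrace(win, binWidth)
  smoothed <- savgolSmooth(binned, windowS = sgWindow)
  detr <- detrendLinearMedian(smoothed, anchorWidth = 30)
  z <- tryCatch(zscoreBaseline(detr, baselineWindow = c(on - 10, on)),
                error = function(e) NULL)
  if (is.null(z)) {
    # flat baseline: no variability to z-score against; the trial carries
    # no response (peak z = 0) and both fits are degenerate
    flat <- new("ZScoredTrace", values = numeric(length(traceValues(detr))),
                samplingRate = samplingRate(detr), t0 = detr@t0,
                baselineMedian = stats::median(traceValues(detr)),
                baselineSd = 1, baselineWindow = c(on - 10, on))
    return(new("StimResponse", peakZ = 0,
               riseFit = new("KineticsFit", direction = "rise"),
               decayFit = new("KineticsFit", direction = "decay"),
               excluded = TRUE, zTrace = flat))
  }
  zt <- traceTimes(z); zv <- traceValues(z)
  laserOn <- zv[zt >= on - binWidth / 2 & zt <= off + binWidth / 2]
  peakZ <- max(laserOn)
  # rise fit: onset to onset + riseWindow, 4-s Savitzky-Golay then fit
  riseIdx <- which(zt >= on & zt <= on + riseWindow)
  riseTr <- FluorescenceTrace(zv[riseIdx], samplingRate = samplingRate(z),
                              t0 = zt[riseIdx[1]])
  riseFit <- fitExpAssociation(savgolSmooth(riseTr, windowS = sgWindow),
                               "rise")
  # decay fit: offset to the post-offset minimum
  postIdx <- which(zt >= off)
  imin <- postIdx[which.min(zv[postIdx])]
  decIdx <- postIdx[postIdx <= imin]
  decayFit <- if (length(decIdx) >= 10) {
    decTr <- FluorescenceTrace(zv[decIdx], samplingRate = samplingRate(z),
                               t0 = zt[decIdx[1]])
    if (smoothDecay && length(decIdx) > sgWindow / binWidth)
      decTr <- savgolSmooth(decTr, windowS = sgWindow)
    fitExpAssociation(decTr, "decay")
  } else new("KineticsFit", direction = "decay")
  bad <- function(f) !isConverged(f) || !is.finite(f@rSquared) ||
    f@rSquared < minR2
  new("StimResponse", peakZ = peakZ, riseFit = riseFit,
      decayFit = decayFit, excluded = bad(riseFit) || bad(decayFit),
      zTrace = z)
}

#' Compare pre-event and event-period fluorescence
#'
#' For a behavioural event (for example, tail lifting) returns the mean
#' dF/F0 of the 5 s preceding the event and of the event period itself,
#' plus the trace normalized by the pre-event standard deviation.
#'
#' @param dff a \linkS4class{DffTrace}.
#' @param eventOnset event onset, s.
#' @param pre pre-event window duration, s.
#' @param eventDur event duration, s.
#' @return list with \code{preMean}, \code{eventMean} and
#'   \code{normalizedTrace} (a \linkS4class{FluorescenceTrace} in units of
#'   pre-event s.d.).
#' @export
eventLockedComparison <- function(dff, eventOnset, pre = 5, eventDur = 10) {
  stopifnot(is(dff, "DffTrace"))
  tt <- traceTimes(dff); v <- traceValues(dff)
  if (eventOnset - pre < tt[1] - 1e-9 ||
      eventOnset + eventDur > tt[length(tt)] + 1 / samplingRate(dff) + 1e-9)
    stop("event window [onset - ", pre, ", onset + ", eventDur,
         "] not covered by the trace")
  preIdx <- which(tt >= eventOnset - pre & tt < eventOnset)
  evIdx <- which(tt >= eventOnset & tt < eventOnset + eventDur)
  s <- stats::sd(v[preIdx])
  norm <- if (is.finite(s) && s > 0) v / s else rep(NA_real_, length(v))
  list(preMean = mean(v[preIdx]), eventMean = mean(v[evIdx]),
       normalizedTrace = FluorescenceTrace(norm,
         samplingRate = samplingRate(dff), t0 = dff@t0))
}

## epoch boundaries of a given transition type; returns times in seconds
.transitionTimes <- function(hypnogram, from, to) {
  st <- hypnogramStates(hypnogram)
  eL <- epochLength(hypnogram)
  i <- which(st[-length(st)] == from & st[-1] == to)
  i * eL                                # boundary between epoch i and i+1
}

#' Sleep-state transition amplitude of the sensor signal
#'
#' For every transition of the requested type, computes the signal change
#' over the surrounding +/-15 s: by default the unsigned range
#' (max - min) of dF/F0 over [t - 15 s, t + 15 s] (the published
#' "maximum and minimum of the 15-s time point before and after the state
#' transition" quantification); \code{method = "twoWindow"} instead returns
#' |mean(post) - mean(pre)|. Transitions closer than 15 s to either edge of
#' the trace are skipped with a warning.
#'
#' @param dff a \linkS4class{DffTrace}, time-aligned with the hypnogram
#'   (both start at t = 0).
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param transitionType one of "NREM->REM", "REM->wake", "wake->NREM",
#'   "NREM->wake".
#' @param halfWindow half-window, s (default 15).
#' @param method "range" (default) or "twoWindow".
#' @return data.frame with columns \code{time} and \code{delta}; empty when
#'   no transitions of the type exist.
#' @export
stateTransitionDeltas <- function(dff, hypnogram,
    transitionType = c("NREM->REM", "REM->wake", "wake->NREM",
                       "NREM->wake"),
    halfWindow = 15, method = c("range", "twoWindow")) {
  stopifnot(is(dff, "DffTrace"), is(hypnogram, "Hypnogram"))
  transitionType <- match.arg(transitionType)
  method <- match.arg(method)
  parts <- strsplit(transitionType, "->", fixed = TRUE)[[1]]
  times <- .transitionTimes(hypnogram, parts[1], parts[2])
  tt <- traceTimes(dff); v <- traceValues(dff)
  out <- data.frame(time = numeric(0), delta = numeric(0))
  for (tr in times) {
    if (tr - halfWindow < tt[1] - 1e-9 ||
        tr + halfWindow > tt[length(tt)] + 1e-9) {
      warning("transition at ", tr, " s skipped: closer than ", halfWindow,
              " s to the trace edge")
      next
    }
    idx <- which(tt >= tr - halfWindow & tt < tr + halfWindow)
    delta <- if (method == "range") max(v[idx]) - min(v[idx])
    else abs(mean(v[idx][tt[idx] >= tr]) - mean(v[idx][tt[idx] < tr]))
    out <- rbind(out, data.frame(time = tr, delta = delta))
  }
  out
}

#' Mean dF/F0 per vigilance state
#'
#' @param dff a \linkS4class{DffTrace} aligned with the hypnogram.
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @return named numeric of mean dF/F0 for wake, NREM and REM; a state with
#'   no epochs (or no covered samples) is NA with a warning.
#' @export
stateMeanDff <- function(dff, hypnogram) {
  stopifnot(is(dff, "DffTrace"), is(hypnogram, "Hypnogram"))
  st <- hypnogramStates(hypnogram)
  eL <- epochLength(hypnogram)
  tt <- traceTimes(dff); v <- traceValues(dff)
  epoch <- floor(tt / eL) + 1L
  ok <- epoch >= 1 & epoch <= length(st)
  out <- vapply(c("wake", "NREM", "REM"), function(s) {
    sel <- ok & st[pmin(pmax(epoch, 1L), length(st))] == s
    if (!any(sel)) NA_real_ else mean(v[sel])
  }, numeric(1))
  if (anyNA(out))
    warning("state(s) absent from the recording: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}
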