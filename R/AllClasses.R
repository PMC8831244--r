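#' @import methods
NULL

## ---------------------------------------------------------------------------
## Trace containers
## ---------------------------------------------------------------------------

#' FluorescenceTrace: a uniformly sampled fluorescence time series
#'
#' The basic container shared by all pipelines. Values are raw fluorescence
#' in arbitrary detector units, sampled at a constant rate. Annotations mark
#' labelled intervals (stimulus trains, ligand additions, behavioural events)
#' in absolute seconds.
#'
#' @slot values numeric vector of fluorescence samples (finite).
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot t0 time of the first sample, in seconds.
#' @slot annotations data.frame with columns \code{label}, \code{start},
#'   \code{end} (seconds); intervals must lie within the trace.
#' @slot metadata free-form list (ground-truth parameters of generated
#'   traces live here).
#'
#' @examples
#' tr <- FluorescenceTrace(rnorm(100, 10), samplingRate = 10)
#' traceTimes(tr)[1:5]
#' @export
setClass("FluorescenceTrace",
  representation(
    values = "numeric",
    samplingRate = "numeric",
    t0 = "numeric",
    annotations = "data.frame",
    metadata = "list"
  ),
  prototype(
    values = numeric(0), samplingRate = 1, t0 = 0,
    annotations = data.frame(label = character(0), start = numeric(0),
                             end = numeric(0)),
    metadata = list()
  )
)

.validTrace <- function(object) {
  msg <- NULL
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  ann <- object@annotations
  if (!all(c("label", "start", "end") %in% names(ann)))
    msg <- c(msg, "'annotations' needs columns label, start, end")
  else if (nrow(ann) > 0L) {
    tend <- object@t0 + length(object@values) / object@samplingRate
    eps <- 1 / object@samplingRate
    if (any(ann$start > ann$end))
      msg <- c(msg, "annotation start must not exceed end")
    if (any(ann$start < object@t0 - eps) || any(ann$end > tend + eps))
      msg <- c(msg, "annotations must lie within the trace time range")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("FluorescenceTrace", .validTrace)

#' @param values,samplingRate,t0,annotations,metadata see slots.
#' @rdname FluorescenceTrace-class
#' @export
FluorescenceTrace <- function(values, samplingRate, t0 = 0,
                              annotations = NULL, metadata = list()) {
  if (is.null(annotations))
    annotations <- data.frame(label = character(0), start = numeric(0),
                              end = numeric(0))
  new("FluorescenceTrace", values = as.numeric(values),
      samplingRate = samplingRate, t0 = t0,
      annotations = annotations, metadata = metadata)
}

#' DffTrace: a baseline-normalized fluorescence trace
#'
#' Holds dF/F0 = (F(t) - F0)/F0 as a dimensionless fraction (multiply by 100
#' for percent), together with the baseline F0 that produced it.
#'
#' @slot baselineValue the baseline fluorescence F0 (> 0).
#' @slot baselineWindow numeric length-2, the (start, end) in seconds of the
#'   baseline samples used.
#' @export
setClass("DffTrace", contains = "FluorescenceTrace",
  representation(baselineValue = "numeric", baselineWindow = "numeric"))

setValidity("DffTrace", function(object) {
  if (length(object@baselineValue) != 1L || object@baselineValue <= 0)
    return("'baselineValue' must be a single positive number")
  if (length(object@baselineWindow) != 2L)
    return("'baselineWindow' must be (start, end)")
  TRUE
})

#' ZScoredTrace: a trace in units of baseline standard deviations
#'
#' Values are (x - median(baseline)) / sd(baseline), with the baseline
#' statistics taken over a stated window (sample, n - 1, standard deviation).
#'
#' @slot baselineMedian median of the baseline window, original units.
#' @slot baselineSd sample standard deviation of the baseline window (> 0).
#' @slot baselineWindow numeric length-2 (start, end) seconds.
#' @export
setClass("ZScoredTrace", contains = "FluorescenceTrace",
  representation(baselineMedian = "numeric", baselineSd = "numeric",
                 baselineWindow = "numeric"))

setValidity("ZScoredTrace", function(object) {
  if (length(object@baselineSd) != 1L || !is.finite(object@baselineSd) ||
      object@baselineSd <= 0)
    return("'baselineSd' must be a single positive number")
  TRUE
})

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' KineticsFit: parameters of a one-phase exponential association or decay
#'
#' Rise: y(t) = offset + amplitude * (1 - exp(-t / tau)).
#' Decay: y(t) = offset + amplitude * exp(-t / tau).
#' Time is measured from the start of the fitted window.
#'
#' @slot tau time constant in seconds (> 0 when converged).
#' @slot amplitude response amplitude in signal units.
#' @slot offset additive offset in signal units.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot converged logical; FALSE flags a failed or degenerate fit (never
#'   reported as silent NaN).
#' @slot direction "rise" or "decay".
#' @export
setClass("KineticsFit",
  representation(tau = "numeric", amplitude = "numeric", offset = "numeric",
                 rSquared = "numeric", converged = "logical",
                 direction = "character"),
  prototype(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
            rSquared = NA_real_, converged = FALSE, direction = "rise"))

setValidity("KineticsFit", function(object) {
  if (isTRUE(object@converged) &&
      (!is.finite(object@tau) || object@tau <= 0))
    return("'tau' must be positive when converged")
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    return("'rSquared' must lie in [0, 1]")
  TRUE
})

#' DoseResponseFit: four-parameter logistic (Hill) dose-response parameters
#'
#' y = bottom + (top - bottom) / (1 + (ec50 / x)^hillSlope), fitted on
#' log10(dose).
#'
#' @slot ec50 half-maximal effective concentration, mol/L (> 0).
#' @slot hillSlope Hill coefficient (dimensionless).
#' @slot top,bottom upper and lower response asymptotes.
#' @slot rSquared coefficient of determination.
#' @slot converged logical convergence flag.
#' @export
setClass("DoseResponseFit",
  representation(ec50 = "numeric", hillSlope = "numeric", top = "numeric",
                 bottom = "numeric", rSquared = "numeric",
                 converged = "logical"),
  prototype(ec50 = NA_real_, hillSlope = NA_real_, top = NA_real_,
            bottom = NA_real_, rSquared = NA_real_, converged = FALSE))

setValidity("DoseResponseFit", function(object) {
  if (isTRUE(object@converged)) {
    if (!is.finite(object@ec50) || object@ec50 <= 0)
      return("'ec50' must be positive when converged")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Imaging containers
## ---------------------------------------------------------------------------

#' ImagingMovie: a motion-corrected two-photon movie
#'
#' Frames are stored as a T x H x W array of non-negative intensities.
#' The anesthetized period is, by convention, the first minute of imaging;
#' \code{anesthesiaOffFrame} records the frame at which anesthetic delivery
#' stopped.
#'
#' @slot frames numeric array, time x rows x columns.
#' @slot frameRate frames per second (typically 4.9-7.5 Hz).
#' @slot pixelSize microns per pixel (typically 1.27).
#' @slot anesthesiaOffFrame frame index (1-based) at anesthesia switch-off.
#' @slot metadata list; generator ground truth lives here.
#' @export
setClass("ImagingMovie",
  representation(frames = "array", frameRate = "numeric",
                 pixelSize = "numeric", anesthesiaOffFrame = "numeric",
                 metadata = "list"),
  prototype(frames = array(0, c(1, 1, 1)), frameRate = 5, pixelSize = 1.27,
            anesthesiaOffFrame = 1, metadata = list()))

setValidity("ImagingMovie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("'frames' must be a T x H x W array")
  if (!all(is.finite(object@frames)) || any(object@frames < 0))
    return("frame intensities must be finite and non-negative")
  if (object@frameRate <= 0)
    return("'frameRate' must be positive")
  if (object@anesthesiaOffFrame < 1 || object@anesthesiaOffFrame > d[1])
    return("'anesthesiaOffFrame' must index a frame of the movie")
  TRUE
})

#' @param frames,frameRate,pixelSize,anesthesiaOffFrame,metadata see slots.
#' @rdname ImagingMovie-class
#' @export
ImagingMovie <- function(frames, frameRate, pixelSize = 1.27,
                         anesthesiaOffFrame = 1, metadata = list()) {
  new("ImagingMovie", frames = frames, frameRate = frameRate,
      pixelSize = pixelSize, anesthesiaOffFrame = anesthesiaOffFrame,
      metadata = metadata)
}

#' BinarizedMovie: pixelwise binarized activity over an analysis window
#'
#' b(i, j, t) = 1 where the raw pixel exceeded its temporal median plus one
#' temporal standard deviation over the window, 0 otherwise. Only the frames
#' of the analysis window are kept.
#'
#' @slot frames T' x H x W array of 0/1 values.
#' @slot window integer length-2: (start frame, end frame) in the source
#'   movie, inclusive.
#' @export
setClass("BinarizedMovie",
  representation(frames = "array", window = "numeric"))

setValidity("BinarizedMovie", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("'frames' must be a T x H x W array")
  if (!all(object@frames %in% c(0, 1)))
    return("binarized frames must contain only 0 and 1")
  if (length(object@window) != 2L || object@window[1] > object@window[2])
    return("'window' must be (start, end) with start <= end")
  if (dim(object@frames)[1] != object@window[2] - object@window[1] + 1)
    return("number of frames must equal the window length")
  TRUE
})

#' MostActiveWindow: the one-minute window of highest spatial variability
#'
#' @slot startFrame first frame (1-based) of the selected window.
#' @slot nFrames number of frames per minute at the movie's frame rate.
#' @slot meanSpatialSd mean over the window of the per-frame spatial
#'   standard deviation of pixel values.
#' @export
setClass("MostActiveWindow",
  representation(startFrame = "numeric", nFrames = "numeric",
                 meanSpatialSd = "numeric"))

#' RoiSet: circular regions of interest with traces and class labels
#'
#' @slot rois data.frame with columns \code{row}, \code{col} (center, 1-based
#'   pixels), \code{radius} (pixels) and \code{class} ("active"/"inactive").
#' @slot traces matrix, frames x ROI, raw-fluorescence ROI means.
#' @slot projection the deconvolved average-projection image the ROIs were
#'   placed on.
#' @slot percentiles named numeric: pooled-distribution cut points p5, p70.
#' @export
setClass("RoiSet",
  representation(rois = "data.frame", traces = "matrix",
                 projection = "matrix", percentiles = "numeric"))

setValidity("RoiSet", function(object) {
  if (nrow(object@rois) > 0 &&
      !all(object@rois$class %in% c("active", "inactive")))
    return("ROI class must be 'active' or 'inactive'")
  TRUE
})

## ---------------------------------------------------------------------------
## Behaviour / physiology containers
## ---------------------------------------------------------------------------

#' EncoderStream: rotary-encoder state-change timestamps
#'
#' The treadmill encoder emits one state change per degree of rotation; each
#' change corresponds to a fixed walked distance (default 2.0 mm, so that the
#' published bout criterion of 65 changes equals 13 cm).
#'
#' @slot eventTimes sorted numeric vector of state-change times, seconds.
#' @slot mmPerChange distance per state change in millimetres (> 0).
#' @slot duration recording duration in seconds.
#' @export
setClass("EncoderStream",
  representation(eventTimes = "numeric", mmPerChange = "numeric",
                 duration = "numeric"),
  prototype(eventTimes = numeric(0), mmPerChange = 2.0, duration = 0))

setValidity("EncoderStream", function(object) {
  if (is.unsorted(object@eventTimes))
    return("'eventTimes' must be sorted")
  if (length(object@eventTimes) &&
      (min(object@eventTimes) < 0 || max(object@eventTimes) > object@duration))
    return("'eventTimes' must lie within [0, duration]")
  if (object@mmPerChange <= 0)
    return("'mmPerChange' must be positive")
  TRUE
})

#' @param eventTimes,mmPerChange,duration see slots.
#' @rdname EncoderStream-class
#' @export
EncoderStream <- function(eventTimes, duration, mmPerChange = 2.0) {
  new("EncoderStream", eventTimes = as.numeric(eventTimes),
      mmPerChange = mmPerChange, duration = duration)
}

#' Hypnogram: per-epoch vigilance-state sequence
#'
#' @slot epochLength epoch duration in seconds (scoring used 1-s epochs).
#' @slot states character vector of "wake", "NREM", "REM" labels; epoch k
#'   covers [(k - 1) * epochLength, k * epochLength) from time zero.
#' @export
setClass("Hypnogram",
  representation(epochLength = "numeric", states = "character"),
  prototype(epochLength = 1, states = character(0)))

setValidity("Hypnogram", function(object) {
  if (length(object@states) == 0L)
    return("'states' must be nonempty")
  if (object@epochLength <= 0)
    return("'epochLength' must be positive")
  if (!all(object@states %in% c("wake", "NREM", "REM")))
    return("states must be 'wake', 'NREM' or 'REM'")
  TRUE
})

#' @param states,epochLength see slots.
#' @rdname Hypnogram-class
#' @export
Hypnogram <- function(states, epochLength = 1) {
  new("Hypnogram", states = states, epochLength = epochLength)
}

#' StimTrain: an optogenetic pulse-train descriptor
#'
#' @slot onset train onset, seconds (absolute trace time).
#' @slot frequency pulse frequency, Hz.
#' @slot pulseWidth single pulse width, seconds (duty cycle must not
#'   exceed 1).
#' @slot duration train duration, seconds.
#' @export
setClass("StimTrain",
  representation(onset = "numeric", frequency = "numeric",
                 pulseWidth = "numeric", duration = "numeric"),
  prototype(onset = 0, frequency = 20, pulseWidth = 0.005, duration = 30))

setValidity("StimTrain", function(object) {
  if (object@frequency * object@pulseWidth > 1)
    return("duty cycle frequency * pulseWidth must not exceed 1")
  if (object@duration <= 0)
    return("'duration' must be positive")
  TRUE
})

#' @param onset,frequency,pulseWidth,duration see slots.
#' @rdname StimTrain-class
#' @export
StimTrain <- function(onset, frequency = 20, pulseWidth = 0.005,
                      duration = 30) {
  new("StimTrain", onset = onset, frequency = frequency,
      pulseWidth = pulseWidth, duration = duration)
}

#' StimResponse: result of a single optogenetic stimulation trial
#'
#' @slot peakZ maximum z-scored fluorescence during the laser-on period.
#' @slot riseFit,decayFit \linkS4class{KineticsFit} of the response onset and
#'   offset phases.
#' @slot excluded TRUE when either fit fails the quality rule.
#' @slot zTrace the processed (binned, smoothed, detrended, z-scored)
#'   \linkS4class{ZScoredTrace} of the trial window.
#' @export
setClass("StimResponse",
  representation(peakZ = "numeric", riseFit = "KineticsFit",
                 decayFit = "KineticsFit", excluded = "logical",
                 zTrace = "ZScoredTrace"))

## ---------------------------------------------------------------------------
## Line-scan containers
## ---------------------------------------------------------------------------

#' LineScanRecording: dual-channel high-speed line scan
#'
#' Green (sensor) and red (arrival dye) channels acquired simultaneously in
#' line-scan mode, pixels x time, typically at 550 Hz.
#'
#' @slot green,red numeric matrices, pixels x time, same shape.
#' @slot samplingRate line rate in Hz.
#' @slot ligandLabel free-text ligand name.
#' @slot metadata list (generator ground truth).
#' @export
setClass("LineScanRecording",
  representation(green = "matrix", red = "matrix", samplingRate = "numeric",
                 ligandLabel = "character", metadata = "list"),
  prototype(samplingRate = 550, ligandLabel = "", metadata = list()))

setValidity("LineScanRecording", function(object) {
  if (!identical(dim(object@green), dim(object@red)))
    return("'green' and 'red' must have identical dimensions")
  if (object@samplingRate <= 0)
    return("'samplingRate' must be positive")
  TRUE
})

#' @param green,red,samplingRate,ligandLabel,metadata see slots.
#' @rdname LineScanRecording-class
#' @export
LineScanRecording <- function(green, red, samplingRate = 550,
                              ligandLabel = "", metadata = list()) {
  new("LineScanRecording", green = green, red = red,
      samplingRate = samplingRate, ligandLabel = ligandLabel,
      metadata = metadata)
}

#' PixelClassMap: membrane/cytosol classification of line-scan pixels
#'
#' @slot classes character vector, one of "membrane", "cytosol", "invalid"
#'   per pixel ("invalid" marks pixels with non-positive pre-ligand mean).
#' @slot thresholdUsed the fractional-change threshold applied.
#' @export
setClass("PixelClassMap",
  representation(classes = "character", thresholdUsed = "numeric"))

setValidity("PixelClassMap", function(object) {
  if (!all(object@classes %in% c("membrane", "cytosol", "invalid")))
    return("classes must be 'membrane', 'cytosol' or 'invalid'")
  TRUE
})
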