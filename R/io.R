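## Readers and writers for the plain-text interchange formats (CSV traces
## with JSON sidecars, multi-page 16-bit TIFF movies with JSON sidecars,
## hypnogram and encoder CSVs), pipeline configuration and the pipeline
## driver.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a fluorescence trace as CSV plus JSON sidecar
#'
#' The CSV holds columns \code{time_s,value}; the sidecar (same path with
#' \code{.json} appended) holds \code{sampling_rate}, \code{t0} and the
#' annotation table. Reading checks that timestamps are uniform.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param path CSV file path.
#' @return \code{writeTrace} returns \code{path} invisibly;
#'   \code{readTrace} returns a \linkS4class{FluorescenceTrace}.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "FluorescenceTrace"))
  utils::write.csv(data.frame(time_s = traceTimes(trace),
                              value = traceValues(trace)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = samplingRate(trace),
                            t0 = trace@t0,
                            annotations = annotations(trace)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns time_s,value")
  if (nrow(df) >= 3) {
    dt <- diff(df$time_s)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-12)
      stop("non-uniform timestamps in ", path)
  }
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    ann <- if (length(meta$annotations))
      as.data.frame(meta$annotations) else NULL
    FluorescenceTrace(df$value, samplingRate = meta$sampling_rate,
                      t0 = meta$t0, annotations = ann)
  } else {
    if (nrow(df) < 2) stop("cannot infer sampling rate from ", path)
    FluorescenceTrace(df$value, samplingRate = 1 / stats::median(diff(df$time_s)),
                      t0 = df$time_s[1])
  }
}

#' Write / read an imaging movie as multi-page 16-bit TIFF plus sidecar
#'
#' Intensities are stored as 16-bit integers (values are rounded and must
#' fit 0..65535); frame rate, pixel size and the anesthesia switch-off
#' frame go to the JSON sidecar. Integer intensities round-trip exactly.
#'
#' @param movie an \linkS4class{ImagingMovie}.
#' @param path TIFF file path.
#' @return \code{writeMovie} returns \code{path} invisibly;
#'   \code{readMovie} an \linkS4class{ImagingMovie}.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "ImagingMovie"))
  fr <- movieFrames(movie)
  if (max(fr) > 65535)
    stop("intensities exceed the 16-bit range")
  pages <- lapply(seq_len(dim(fr)[1]),
                  function(i) round(fr[i, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(frame_rate = frameRate(movie),
                            pixel_size_um = pixelSize(movie),
                            anesthesia_off_frame = anesthesiaOffFrame(movie)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMovie
#' @export
readMovie <- function(path) {
  side <- .sidecarPath(path)
  if (!file.exists(side))
    stop("missing sidecar ", side, "; required fields: frame_rate, ",
         "pixel_size_um, anesthesia_off_frame")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("frame_rate", "pixel_size_um", "anesthesia_off_frame")
  if (!all(need %in% names(meta)))
    stop("sidecar must provide: ", paste(need, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d))
      stop("inconsistent frame shapes in ", path)
    frames[i, , ] <- round(pages[[i]] * 65535)
  }
  ImagingMovie(frames, frameRate = meta$frame_rate,
               pixelSize = meta$pixel_size_um,
               anesthesiaOffFrame = meta$anesthesia_off_frame)
}

#' Read a hypnogram CSV
#'
#' Expects columns \code{epoch_index,state} with states coded W/N/R (or
#' spelled out); epochs must be consecutive from 1.
#'
#' @param path CSV path.
#' @param epochLength epoch length in seconds (default 1).
#' @return a \linkS4class{Hypnogram}.
#' @export
readHypnogram <- function(path, epochLength = 1) {
  df <- utils::read.csv(path)
  if (!all(c("epoch_index", "state") %in% names(df)))
    stop("hypnogram CSV must have columns epoch_index,state")
  df <- df[order(df$epoch_index), ]
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df))))
    stop("epoch_index must be consecutive from 1")
  map <- c(W = "wake", N = "NREM", R = "REM",
           wake = "wake", NREM = "NREM", REM = "REM")
  st <- map[as.character(df$state)]
  if (anyNA(st)) stop("unrecognized state code in ", path)
  Hypnogram(unname(st), epochLength = epochLength)
}

#' Write a hypnogram CSV (epoch_index,state with W/N/R codes)
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeHypnogram <- function(hypnogram, path) {
  code <- c(wake = "W", NREM = "N", REM = "R")
  utils::write.csv(data.frame(
    epoch_index = seq_along(hypnogramStates(hypnogram)),
    state = unname(code[hypnogramStates(hypnogram)])),
    path, row.names = FALSE)
  invisible(path)
}

#' Read / write rotary-encoder state-change times (CSV, column event_time_s)
#'
#' @param stream an \linkS4class{EncoderStream}.
#' @param path CSV path.
#' @param duration recording duration in seconds; when NULL, taken from the
#'   sidecar if present, else the last event time rounded up.
#' @param mmPerChange distance per state change, mm.
#' @return \code{readEncoder} returns an \linkS4class{EncoderStream}.
#' @export
writeEncoder <- function(stream, path) {
  utils::write.csv(data.frame(event_time_s = eventTimes(stream)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(duration = stream@duration,
                            mm_per_change = stream@mmPerChange),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEncoder
#' @export
readEncoder <- function(path, duration = NULL, mmPerChange = NULL) {
  df <- utils::read.csv(path)
  if (!"event_time_s" %in% names(df))
    stop("encoder CSV must have column event_time_s")
  side <- .sidecarPath(path)
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (is.null(duration))
    duration <- if (!is.null(meta$duration)) meta$duration
                else ceiling(max(df$event_time_s, 0))
  if (is.null(mmPerChange))
    mmPerChange <- if (!is.null(meta$mm_per_change)) meta$mm_per_change
                   else 2.0
  EncoderStream(df$event_time_s, duration = duration,
                mmPerChange = mmPerChange)
}

## ---------------------------------------------------------------------------
## Pipeline configuration and driver
## ---------------------------------------------------------------------------

.configDefaults <- function() list(
  seed = 1L,
  outputDir = "results",
  logLevel = "info",
  # signal processing
  binWidth = 0.1, sgWindow = 4, sgOrder = 3, anchorWidth = 30,
  dffPoints = 10,
  # photometry trials
  windowPre = 30, windowPost = 90, riseWindow = 10, minR2 = 0.5,
  # locomotion
  minChanges = 65, countWindow = 5, quietWindow = 1, maxQuietChanges = 1,
  mmPerChange = 2.0,
  # two-photon
  nActive = 10, nInactive = 10, diameterPx = 12, rlIterations = 10,
  smoothSigma = 2, psfSize = 39, psfSigma = 20,
  # line scan
  lowpassCutoff = 20, membraneThreshold = 0.5, maxLatency = 0.05
)

#' Build, read or write a pipeline configuration
#'
#' A configuration is a named list of analysis parameters with documented
#' defaults (see \code{pipelineConfig()} for the full set). Unknown keys
#' are rejected; configurations round-trip through JSON unchanged.
#'
#' @param ... named parameters overriding the defaults.
#' @param config a configuration list.
#' @param path JSON file path.
#' @return \code{pipelineConfig} and \code{readPipelineConfig} return the
#'   validated configuration list.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  def <- .configDefaults()
  unknown <- setdiff(names(over), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  def[names(over)] <- over
  def
}

#' @rdname pipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

.logLine <- function(logFile, ...) {
  cat(format(Sys.time(), "%H:%M:%S"), paste0(...), "\n",
      file = logFile, append = TRUE)
}

#' Run analysis pipeline stages on seeded synthetic data
#'
#' Executes the requested stages end to end: each stage generates its input
#' with the corresponding seeded generator (substream seeds derived from
#' \code{config$seed} via \code{\link{splitSeed}}), runs the analysis and
#' writes machine-readable CSV/JSON results plus a log into
#' \code{config$outputDir}. Identical configuration and seed reproduce
#' identical outputs. Stages: \code{generate} (write raw synthetic fixtures),
#' \code{invitro} (dF/F0 + dose-response), \code{photometry} (stimulation
#' trial), \code{locomotion} (bout detection and regression),
#' \code{twophoton} (full ROI pipeline), \code{linescan} (kinetics).
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @param stages character vector of stage names.
#' @param movieSize two-photon synthetic movie edge length, px (kept
#'   moderate by default so a full run stays interactive).
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("invitro", "photometry", "locomotion",
                                   "linescan"),
                        movieSize = 96) {
  ok <- c("generate", "invitro", "photometry", "locomotion", "twophoton",
          "linescan")
  bad <- setdiff(stages, ok)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outputDir, "pipeline.log")
  writePipelineConfig(config, file.path(config$outputDir, "config.json"))
  .logLine(logFile, "seed=", config$seed)
  seed <- config$seed
  for (st in stages) {
    .logLine(logFile, "stage ", st, " start")
    switch(st,
      generate = {
        writeTrace(genPhotometry(splitSeed(seed, 11)),
                   file.path(config$outputDir, "photometry.csv"))
        writeEncoder(genEncoder(splitSeed(seed, 12),
            bouts = data.frame(onset = c(20, 60), duration = 5,
                               rate = 30)),
          file.path(config$outputDir, "encoder.csv"))
        hg <- genHypnogram(splitSeed(seed, 13))
        writeHypnogram(hg$hypnogram,
                       file.path(config$outputDir, "hypnogram.csv"))
        mv <- genMovie(splitSeed(seed, 14), width = movieSize,
                       height = movieSize)
        writeMovie(mv, file.path(config$outputDir, "movie.tif"))
      },
      invitro = {
        dr <- genDoseResponse(splitSeed(seed, 21))
        fit <- fit4PL(dr$doses, dr$responses)
        jsonlite::write_json(as.list(fitParameters(fit)),
          file.path(config$outputDir, "dose_response_fit.json"),
          auto_unbox = TRUE, digits = NA)
      },
      photometry = {
        tr <- genPhotometry(splitSeed(seed, 31))
        stim <- traceMetadata(tr)$groundTruth$trains[[1]]
        res <- analyzeStimTrial(tr, stim, windowPre = config$windowPre,
          windowPost = config$windowPost, binWidth = config$binWidth,
          sgWindow = config$sgWindow, riseWindow = config$riseWindow,
          minR2 = config$minR2)
        jsonlite::write_json(list(peak_z = res@peakZ,
            tau_rise = res@riseFit@tau, tau_decay = res@decayFit@tau,
            excluded = res@excluded),
          file.path(config$outputDir, "stim_trial.json"),
          auto_unbox = TRUE, digits = NA)
      },
      locomotion = {
        es <- genEncoder(splitSeed(seed, 41),
          bouts = data.frame(onset = c(20, 60, 95), duration = 5,
                             rate = 30))
        onsets <- detectRunBouts(es, minChanges = config$minChanges,
          countWindow = config$countWindow,
          quietWindow = config$quietWindow,
          maxQuietChanges = config$maxQuietChanges)
        speed <- encoderToSpeed(es, binWidth = config$binWidth)
        utils::write.csv(data.frame(onset_s = onsets),
          file.path(config$outputDir, "bouts.csv"), row.names = FALSE)
        writeTrace(speed, file.path(config$outputDir, "speed.csv"))
      },
      twophoton = {
        mv <- genMovie(splitSeed(seed, 14), width = movieSize,
                       height = movieSize)
        res <- twoPhotonRoiPipeline(mv, nActive = config$nActive,
          nInactive = config$nInactive, diameterPx = config$diameterPx,
          iterations = config$rlIterations)
        utils::write.csv(roiTable(res$roiset),
          file.path(config$outputDir, "rois.csv"), row.names = FALSE)
        utils::write.csv(as.data.frame(res$correlations$matrix),
          file.path(config$outputDir, "roi_correlations.csv"),
          row.names = FALSE)
        dff <- fovDffTrace(mv)
        jsonlite::write_json(list(
            first_last_delta = firstLastMinuteDelta(dff),
            n_rois = nrow(roiTable(res$roiset)),
            mean_active_r = res$correlations$meanActiveR,
            mean_inactive_r = res$correlations$meanInactiveR),
          file.path(config$outputDir, "twophoton_summary.json"),
          auto_unbox = TRUE, digits = NA)
      },
      linescan = {
        rec <- genLinescan(splitSeed(seed, 51))
        gt <- rec@metadata$groundTruth
        cm <- classifyMembranePixels(rec,
          preWindow = c(0, gt$arrivalTime),
          postWindow = c(gt$arrivalTime + 2, ncol(rec@green) /
                           rec@samplingRate),
          thresholdFrac = config$membraneThreshold)
        fit <- fitPixelTaus(rec, cm, lowpassCutoff = config$lowpassCutoff,
                            maxLatency = config$maxLatency)
        jsonlite::write_json(list(tau_mean = fit$tauMean,
            latency = fit$latency, gate_passed = fit$gatePassed),
          file.path(config$outputDir, "linescan_kinetics.json"),
          auto_unbox = TRUE, digits = NA)
      })
    .logLine(logFile, "stage ", st, " done")
  }
  invisible(config$outputDir)
}
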