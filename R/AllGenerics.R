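## Accessor generics and show methods. Slots are never accessed with @ by
## user code; these accessors are the supported surface.

#' @rdname FluorescenceTrace-class
#' @param object,x a \linkS4class{FluorescenceTrace} (or subclass).
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname FluorescenceTrace-class
#' @export
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname FluorescenceTrace-class
#' @export
setMethod("samplingRate", "FluorescenceTrace", function(x) x@samplingRate)

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname FluorescenceTrace-class
#' @export
setMethod("traceTimes", "FluorescenceTrace", function(x)
  x@t0 + (seq_along(x@values) - 1L) / x@samplingRate)

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))
#' @rdname FluorescenceTrace-class
#' @export
setMethod("traceDuration", "FluorescenceTrace", function(x)
  length(x@values) / x@samplingRate)

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname FluorescenceTrace-class
#' @export
setMethod("annotations", "FluorescenceTrace", function(x) x@annotations)

#' @rdname FluorescenceTrace-class
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @rdname FluorescenceTrace-class
#' @export
setMethod("traceMetadata", "FluorescenceTrace", function(x) x@metadata)

#' @rdname DffTrace-class
#' @param x a \linkS4class{DffTrace}.
#' @export
setGeneric("baselineValue", function(x) standardGeneric("baselineValue"))
#' @rdname DffTrace-class
#' @export
setMethod("baselineValue", "DffTrace", function(x) x@baselineValue)

#' @rdname ZScoredTrace-class
#' @param x a trace with a recorded baseline window.
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))
#' @rdname ZScoredTrace-class
#' @export
setMethod("baselineWindow", "ZScoredTrace", function(x) x@baselineWindow)
#' @rdname DffTrace-class
#' @export
setMethod("baselineWindow", "DffTrace", function(x) x@baselineWindow)

#' @rdname ZScoredTrace-class
#' @param object a \linkS4class{ZScoredTrace}.
#' @export
setGeneric("baselineStats", function(x) standardGeneric("baselineStats"))
#' @rdname ZScoredTrace-class
#' @export
setMethod("baselineStats", "ZScoredTrace", function(x)
  c(median = x@baselineMedian, sd = x@baselineSd))

#' @rdname ImagingMovie-class
#' @param x an \linkS4class{ImagingMovie} or \linkS4class{BinarizedMovie}.
#' @export
setGeneric("movieFrames", function(x) standardGeneric("movieFrames"))
#' @rdname ImagingMovie-class
#' @export
setMethod("movieFrames", "ImagingMovie", function(x) x@frames)
#' @rdname BinarizedMovie-class
#' @param x a \linkS4class{BinarizedMovie}.
#' @export
setMethod("movieFrames", "BinarizedMovie", function(x) x@frames)

#' @rdname ImagingMovie-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname ImagingMovie-class
#' @export
setMethod("frameRate", "ImagingMovie", function(x) x@frameRate)

#' @rdname ImagingMovie-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname ImagingMovie-class
#' @export
setMethod("pixelSize", "ImagingMovie", function(x) x@pixelSize)

#' @rdname ImagingMovie-class
#' @export
setGeneric("anesthesiaOffFrame",
           function(x) standardGeneric("anesthesiaOffFrame"))
#' @rdname ImagingMovie-class
#' @export
setMethod("anesthesiaOffFrame", "ImagingMovie",
          function(x) x@anesthesiaOffFrame)

#' @rdname ImagingMovie-class
#' @export
setGeneric("movieMetadata", function(x) standardGeneric("movieMetadata"))
#' @rdname ImagingMovie-class
#' @export
setMethod("movieMetadata", "ImagingMovie", function(x) x@metadata)

#' @rdname MostActiveWindow-class
#' @param x a \linkS4class{MostActiveWindow}.
#' @export
setGeneric("windowFrames", function(x) standardGeneric("windowFrames"))
#' @rdname MostActiveWindow-class
#' @export
setMethod("windowFrames", "MostActiveWindow", function(x)
  c(start = x@startFrame, end = x@startFrame + x@nFrames - 1))

#' @rdname RoiSet-class
#' @param x a \linkS4class{RoiSet}.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
#' @rdname RoiSet-class
#' @export
setMethod("roiTable", "RoiSet", function(x) x@rois)

#' @rdname RoiSet-class
#' @export
setGeneric("roiTraces", function(x) standardGeneric("roiTraces"))
#' @rdname RoiSet-class
#' @export
setMethod("roiTraces", "RoiSet", function(x) x@traces)

#' @rdname RoiSet-class
#' @export
setGeneric("roiPercentiles", function(x) standardGeneric("roiPercentiles"))
#' @rdname RoiSet-class
#' @export
setMethod("roiPercentiles", "RoiSet", function(x) x@percentiles)

#' @rdname EncoderStream-class
#' @param x an \linkS4class{EncoderStream}.
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname EncoderStream-class
#' @export
setMethod("eventTimes", "EncoderStream", function(x) x@eventTimes)

#' @rdname Hypnogram-class
#' @param x a \linkS4class{Hypnogram}.
#' @export
setGeneric("hypnogramStates", function(x) standardGeneric("hypnogramStates"))
#' @rdname Hypnogram-class
#' @export
setMethod("hypnogramStates", "Hypnogram", function(x) x@states)

#' @rdname Hypnogram-class
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))
#' @rdname Hypnogram-class
#' @export
setMethod("epochLength", "Hypnogram", function(x) x@epochLength)

#' @rdname KineticsFit-class
#' @param x a \linkS4class{KineticsFit} or \linkS4class{DoseResponseFit}.
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))
#' @rdname KineticsFit-class
#' @export
setMethod("fitParameters", "KineticsFit", function(x)
  c(tau = x@tau, amplitude = x@amplitude, offset = x@offset,
    rSquared = x@rSquared))
#' @rdname DoseResponseFit-class
#' @param x a \linkS4class{DoseResponseFit}.
#' @export
setMethod("fitParameters", "DoseResponseFit", function(x)
  c(ec50 = x@ec50, hillSlope = x@hillSlope, top = x@top, bottom = x@bottom,
    rSquared = x@rSquared))

#' @rdname KineticsFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname KineticsFit-class
#' @export
setMethod("isConverged", "KineticsFit", function(x) x@converged)
#' @rdname DoseResponseFit-class
#' @export
setMethod("isConverged", "DoseResponseFit", function(x) x@converged)

## -- show methods -----------------------------------------------------------

setMethod("show", "FluorescenceTrace", function(object) {
  cat(class(object), "with", length(object@values), "samples at",
      object@samplingRate, "Hz (",
      sprintf("%.2f", length(object@values) / object@samplingRate),
      "s )\n")
  if (nrow(object@annotations))
    cat("  annotations:",
        paste(object@annotations$label, collapse = ", "), "\n")
})

setMethod("show", "KineticsFit", function(object) {
  cat("KineticsFit (", object@direction, "): tau =",
      signif(object@tau, 4), "s, amplitude =", signif(object@amplitude, 4),
      ", R2 =", signif(object@rSquared, 3),
      if (object@converged) "" else "[not converged]", "\n")
})

setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit: EC50 =", signif(object@ec50, 4),
      "mol/L, Hill =", signif(object@hillSlope, 3),
      ", top =", signif(object@top, 3),
      ", bottom =", signif(object@bottom, 3),
      if (object@converged) "" else "[not converged]", "\n")
})

setMethod("show", "ImagingMovie", function(object) {
  d <- dim(object@frames)
  cat("ImagingMovie:", d[1], "frames of", d[2], "x", d[3], "px at",
      object@frameRate, "Hz,", object@pixelSize, "um/px\n")
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet:", sum(object@rois$class == "active"), "active +",
      sum(object@rois$class == "inactive"), "inactive circular ROIs\n")
})

setMethod("show", "EncoderStream", function(object) {
  cat("EncoderStream:", length(object@eventTimes), "state changes over",
      object@duration, "s (", object@mmPerChange, "mm/change )\n")
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@states, c("wake", "NREM", "REM")))
  cat("Hypnogram:", length(object@states), "epochs of",
      object@epochLength, "s;", paste(names(tab), tab, collapse = ", "),
      "\n")
})

setMethod("show", "MostActiveWindow", function(object) {
  cat("MostActiveWindow: frames", object@startFrame, "-",
      object@startFrame + object@nFrames - 1,
      "( mean spatial s.d.", signif(object@meanSpatialSd, 4), ")\n")
})
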