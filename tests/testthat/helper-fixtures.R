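# shared fixture builders; everything is generated in code

constTrace <- function(value = 5, n = 100, rate = 10) {
  FluorescenceTrace(rep(value, n), samplingRate = rate)
}

# movie whose frames are each spatially constant at the given values
frameValueMovie <- function(values, frameRate, h = 4, w = 4) {
  fr <- array(rep(values, each = 1), c(length(values), h, w))
  for (i in seq_along(values)) fr[i, , ] <- values[i]
  ImagingMovie(fr, frameRate = frameRate)
}

# small movie config for property suites: 72 px, 2 Hz, 6 min, five
# hotspots covering ~19% of the frame (see the methods vignette for why
# these scaled-down study conditions preserve the pipeline's behaviour)
smallHotspotMovie <- function(seed, nHotspots = 5) {
  genMovie(seed, width = 72, height = 72, frameRate = 2, duration = 360,
           nHotspots = nHotspots, hotspotRadius = 8,
           hotspotAmplitude = 100, nVessels = 1)
}

smallControlMovie <- function(seed) {
  genMovie(seed, width = 72, height = 72, frameRate = 2, duration = 360,
           nHotspots = 0, rampAmplitude = 0, nVessels = 1)
}
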