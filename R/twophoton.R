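## The cortical two-photon pipeline: field-of-view dF/F0, most-active-minute
## selection, pixelwise binarization, Gaussian smoothing, Richardson-Lucy
## deconvolution, percentile-band circular ROI identification and pairwise
## correlation analysis.

## frames as a T x (H*W) matrix
.flatFrames <- function(frames) {
  d <- dim(frames)
  dim(frames) <- c(d[1], d[2] * d[3])
  frames
}

#' Field-of-view dF/F0 trace
#'
#' Treats each imaging frame as one ROI containing all pixels: F(t) is the
#' per-frame mean over pixels, and F0 the median of F(t) over the
#' anesthetized period (the first minute of imaging).
#'
#' @param movie an \linkS4class{ImagingMovie} of at least one minute.
#' @return a \linkS4class{DffTrace} sampled at the movie frame rate.
#' @export
fovDffTrace <- function(movie) {
  stopifnot(is(movie, "ImagingMovie"))
  fr <- frameRate(movie)
  nMin <- round(60 * fr)
  d <- dim(movieFrames(movie))
  if (d[1] < nMin)
    stop("movie must cover at least one minute (", nMin, " frames)")
  f <- rowMeans(.flatFrames(movieFrames(movie)))
  f0 <- stats::median(f[seq_len(nMin)])
  if (f0 <= 0) stop("baseline (anesthetized-period median) must be positive")
  new("DffTrace", values = (f - f0) / f0, samplingRate = fr, t0 = 0,
      annotations = data.frame(label = character(0), start = numeric(0),
                               end = numeric(0)),
      metadata = movieMetadata(movie),
      baselineValue = f0, baselineWindow = c(0, 60))
}

#' Difference between last-minute and first-minute mean dF/F0
#'
#' The summary used to quantify the global fluorescence rise on emergence
#' from anesthesia: mean dF/F0 over the final minute minus mean dF/F0 over
#' the first minute.
#'
#' @param dff a \linkS4class{DffTrace} of at least two minutes.
#' @return a single number.
#' @export
firstLastMinuteDelta <- function(dff) {
  stopifnot(is(dff, "DffTrace"))
  n <- length(traceValues(dff))
  nMin <- round(60 * samplingRate(dff))
  if (n < 2 * nMin) stop("trace must cover at least two minutes")
  v <- traceValues(dff)
  mean(v[(n - nMin + 1):n]) - mean(v[seq_len(nMin)])
}

#' Find the most-active minute of a movie
#'
#' Computes the spatial standard deviation of pixel values for every frame
#' in the search period, averages it over a moving one-minute window
#' (advancing one frame per step) and returns the window with the highest
#' average; ties go to the earliest window. The default search period runs
#' from the start of minute 3 to the end of minute 6 of imaging.
#'
#' @param movie an \linkS4class{ImagingMovie}.
#' @param searchStart,searchEnd first and last frame (1-based, inclusive)
#'   of the search period; defaults to minutes 3-6.
#' @return a \linkS4class{MostActiveWindow}.
#' @export
findMostActiveMinute <- function(movie, searchStart = NULL,
                                 searchEnd = NULL) {
  stopifnot(is(movie, "ImagingMovie"))
  fr <- frameRate(movie)
  nT <- dim(movieFrames(movie))[1]
  n <- round(60 * fr)
  if (is.null(searchStart)) searchStart <- round(120 * fr) + 1
  if (is.null(searchEnd)) searchEnd <- min(nT, round(360 * fr))
  searchStart <- max(1L, as.integer(searchStart))
  searchEnd <- min(nT, as.integer(searchEnd))
  if (searchEnd - searchStart + 1 < n)
    stop("search period must be at least one minute (", n, " frames)")
  idx <- searchStart:searchEnd
  sds <- matrixStats::rowSds(.flatFrames(
    movieFrames(movie)[idx, , , drop = FALSE]))
  cs <- cumsum(c(0, sds))
  nWin <- length(idx) - n + 1
  means <- (cs[(n + 1):(n + nWin)] - cs[1:nWin]) / n
  best <- which.max(means)                       # earliest on ties
  new("MostActiveWindow", startFrame = idx[best], nFrames = n,
      meanSpatialSd = means[best])
}

#' Binarize a movie over an analysis window
#'
#' Each pixel is set to 1 in the frames where its raw value strictly
#' exceeds its temporal median plus its temporal (sample) standard
#' deviation over the window, and 0 otherwise. A constant pixel has zero
#' standard deviation and, by the strict inequality, is never set.
#'
#' @param movie an \linkS4class{ImagingMovie}.
#' @param window a \linkS4class{MostActiveWindow} or numeric (start, end)
#'   frame pair, inclusive.
#' @return a \linkS4class{BinarizedMovie} limited to the window frames.
#' @export
binarizeWindow <- function(movie, window) {
  stopifnot(is(movie, "ImagingMovie"))
  w <- if (is(window, "MostActiveWindow")) windowFrames(window)
       else as.numeric(window)
  d <- dim(movieFrames(movie))
  if (w[1] < 1 || w[2] > d[1]) stop("window exceeds the movie")
  sub <- movieFrames(movie)[w[1]:w[2], , , drop = FALSE]
  m <- .flatFrames(sub)
  thr <- matrixStats::colMedians(m) + matrixStats::colSds(m)
  b <- sweep(m, 2, thr, ">") * 1
  dim(b) <- dim(sub)
  new("BinarizedMovie", frames = b, window = as.numeric(w))
}

.gaussianKernel <- function(size, sigma) {
  stopifnot(size %% 2 == 1)
  ax <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  k / sum(k)
}

## Richardson-Lucy iteration; psf is symmetric so the mirrored kernel
## equals the kernel itself. Convolutions are FFT-based with circular
## boundary and run over all frames at once (frames as channels).
.richardsonLucy <- function(observed, psf, iterations) {
  eps <- 1e-12
  est <- observed
  for (i in seq_len(iterations)) {
    denom <- EBImage::filter2(est, psf, boundary = "circular")
    ratio <- observed / pmax(denom, eps)
    est <- est * EBImage::filter2(ratio, psf, boundary = "circular")
  }
  est
}

#' Smooth and deconvolve a binarized movie
#'
#' Applies a 2-D Gaussian filter (s.d. \code{smoothSigma} pixels) to each
#' binarized frame, giving values between 0 and 1, then Richardson-Lucy
#' deconvolution with a Gaussian point-spread function (default 39 x 39
#' pixels, s.d. 20 pixels, i.e. 50 um x 50 um at 1.27 um/px). Returns the
#' deconvolved frames and their average projection; projection values are
#' comparable across fields of view.
#'
#' @param binarized a \linkS4class{BinarizedMovie}.
#' @param smoothSigma Gaussian smoothing s.d., px.
#' @param psfSize point-spread-function side length, px (odd).
#' @param psfSigma point-spread-function s.d., px.
#' @param iterations Richardson-Lucy iterations (default 10).
#' @return list with \code{deconvolved} (T x H x W array) and
#'   \code{projection} (H x W matrix, the mean over frames).
#' @export
smoothAndDeconvolve <- function(binarized, smoothSigma = 2, psfSize = 39,
                                psfSigma = 20, iterations = 10) {
  stopifnot(is(binarized, "BinarizedMovie"))
  d <- dim(movieFrames(binarized))
  if (psfSize > d[2] || psfSize > d[3])
    stop("point-spread function (", psfSize, " px) larger than the frame")
  psf <- .gaussianKernel(psfSize, psfSigma)
  arr <- aperm(movieFrames(binarized), c(2, 3, 1))   # H x W x T
  sm <- EBImage::gblur(arr, sigma = smoothSigma)
  sm <- pmin(pmax(sm, 0), 1)
  dec <- .richardsonLucy(sm, psf, iterations)
  proj <- rowMeans(dec, dims = 2)
  list(deconvolved = aperm(dec, c(3, 1, 2)), projection = proj)
}

.discOffsets <- function(diameterPx) {
  r <- diameterPx / 2
  lim <- floor(r)
  g <- expand.grid(dr = -lim:lim, dc = -lim:lim)
  g[g$dr^2 + g$dc^2 <= (r - 0.5)^2, ]
}

## greedy circular placement: candidates ordered by projection value,
## highest first; a circle is accepted when fully inside the image, not
## overlapping accepted circles, and all its pixels satisfy `bandOk`.
.placeCircles <- function(proj, centerMask, bandOk, offsets, nWanted) {
  H <- nrow(proj); W <- ncol(proj)
  covered <- matrix(FALSE, H, W)
  cand <- which(centerMask)
  cand <- cand[order(proj[cand], decreasing = TRUE)]
  rad <- max(abs(offsets$dr))
  acc <- data.frame(row = integer(0), col = integer(0))
  for (ij in cand) {
    if (nrow(acc) >= nWanted) break
    r0 <- ((ij - 1) %% H) + 1
    c0 <- ((ij - 1) %/% H) + 1
    if (covered[r0, c0]) next
    if (r0 - rad < 1 || r0 + rad > H || c0 - rad < 1 || c0 + rad > W) next
    rr <- r0 + offsets$dr; cc <- c0 + offsets$dc
    lin <- rr + (cc - 1) * H
    if (any(covered[lin]) || !all(bandOk[lin])) next
    covered[lin] <- TRUE
    acc <- rbind(acc, data.frame(row = r0, col = c0))
  }
  list(centers = acc, covered = covered)
}

#' Identify active and inactive circular ROIs on deconvolved projections
#'
#' Percentile bands are computed on the pooled pixel distribution across
#' all supplied projections (linear-interpolation percentiles): pixels at
#' or above the 70th percentile form the active band, pixels from the 5th
#' up to (but excluding) the 69th percentile form the inactive band, and
#' pixels below the 5th percentile (blood vessels) are excluded from every
#' ROI. Per projection, circular ROIs (default diameter 12 px) are placed
#' greedily, highest-valued in-band pixel first: an active ROI must contain
#' no excluded pixel, an inactive ROI must consist entirely of sub-70th
#' percentile, non-excluded pixels; ROIs never overlap. When fewer than the
#' requested number fit, the shortfall is reported with a warning.
#'
#' @param projections a projection matrix or a list of them (one per FOV).
#' @param nActive,nInactive requested ROI counts per FOV (default 10 each).
#' @param diameterPx ROI diameter, px (default 12).
#' @return a \linkS4class{RoiSet} (or list of them when a list was given);
#'   traces are filled later by \code{\link{roiCorrelationAnalysis}}.
#' @export
identifyRois <- function(projections, nActive = 10, nInactive = 10,
                         diameterPx = 12) {
  single <- is.matrix(projections)
  if (single) projections <- list(projections)
  if (!length(projections)) stop("at least one projection is required")
  pooled <- unlist(lapply(projections, as.numeric))
  q <- stats::quantile(pooled, c(0.05, 0.69, 0.70), type = 7, names = FALSE)
  p5 <- q[1]; p69 <- q[2]; p70 <- q[3]
  offs <- .discOffsets(diameterPx)
  sets <- lapply(projections, function(proj) {
    act <- .placeCircles(proj, centerMask = proj >= p70,
                         bandOk = proj >= p5, offs, nActive)
    inactMask <- proj >= p5 & proj < p69 & !act$covered
    inact <- .placeCircles(proj, centerMask = inactMask,
                           bandOk = proj >= p5 & proj < p70 & !act$covered,
                           offs, nInactive)
    nA <- nrow(act$centers); nI <- nrow(inact$centers)
    if (nA < nActive || nI < nInactive)
      warning("placed ", nA, "/", nActive, " active and ", nI, "/",
              nInactive, " inactive ROIs (insufficient qualifying area)")
    rois <- rbind(
      if (nA) data.frame(act$centers, radius = diameterPx / 2,
                         class = "active"),
      if (nI) data.frame(inact$centers, radius = diameterPx / 2,
                         class = "inactive"))
    if (is.null(rois))
      rois <- data.frame(row = integer(0), col = integer(0),
                         radius = numeric(0), class = character(0))
    new("RoiSet", rois = rois, traces = matrix(0, 0, 0),
        projection = proj, percentiles = c(p5 = p5, p69 = p69, p70 = p70))
  })
  if (single) sets[[1]] else sets
}

#' Extract ROI traces and compute pairwise Pearson correlations
#'
#' ROI traces are the per-frame means of the RAW movie pixels inside each
#' circle, over the frames of the analysis window. The full symmetric
#' Pearson correlation matrix is returned together with the mean
#' off-diagonal correlation within the active and within the inactive ROI
#' class. Pairs involving a constant trace are undefined (NA) and excluded
#' from the class means.
#'
#' @param roiset a \linkS4class{RoiSet}.
#' @param movie the raw \linkS4class{ImagingMovie}.
#' @param window a \linkS4class{MostActiveWindow} or (start, end) frames.
#' @return list with \code{matrix} (ROI x ROI Pearson r), \code{meanActiveR},
#'   \code{meanInactiveR} and \code{roiset} (with traces filled in).
#' @export
roiCorrelationAnalysis <- function(roiset, movie, window) {
  stopifnot(is(roiset, "RoiSet"), is(movie, "ImagingMovie"))
  w <- if (is(window, "MostActiveWindow")) windowFrames(window)
       else as.numeric(window)
  fr <- movieFrames(movie)
  if (w[1] < 1 || w[2] > dim(fr)[1]) stop("window exceeds the movie")
  rois <- roiTable(roiset)
  if (!nrow(rois)) stop("empty ROI set")
  offs <- .discOffsets(2 * rois$radius[1])
  H <- dim(fr)[2]
  sub <- .flatFrames(fr[w[1]:w[2], , , drop = FALSE])
  traces <- vapply(seq_len(nrow(rois)), function(k) {
    rr <- rois$row[k] + offs$dr; cc <- rois$col[k] + offs$dc
    rowMeans(sub[, rr + (cc - 1) * H, drop = FALSE])
  }, numeric(w[2] - w[1] + 1))
  sds <- matrixStats::colSds(traces)
  cm <- suppressWarnings(stats::cor(traces))
  cm[sds == 0, ] <- NA; cm[, sds == 0] <- NA
  diag(cm) <- 1
  classMean <- function(cl) {
    i <- which(rois$class == cl)
    if (length(i) < 2) return(NA_real_)
    m <- cm[i, i]
    mean(m[upper.tri(m)], na.rm = TRUE)
  }
  roiset@traces <- traces
  list(matrix = cm, meanActiveR = classMean("active"),
       meanInactiveR = classMean("inactive"), roiset = roiset)
}

#' Run the full two-photon ROI pipeline on one field of view
#'
#' Convenience wrapper: most-active-minute selection, binarization over
#' that window, Gaussian smoothing, Richardson-Lucy deconvolution,
#' percentile-band ROI identification and raw-trace correlation analysis.
#'
#' @param movie an \linkS4class{ImagingMovie}.
#' @param nActive,nInactive,diameterPx ROI parameters.
#' @param iterations Richardson-Lucy iterations.
#' @param searchStart,searchEnd most-active-minute search period (frames).
#' @return list with \code{window}, \code{projection}, \code{roiset},
#'   \code{correlations} (the \code{\link{roiCorrelationAnalysis}} result).
#' @export
twoPhotonRoiPipeline <- function(movie, nActive = 10, nInactive = 10,
                                 diameterPx = 12, iterations = 10,
                                 searchStart = NULL, searchEnd = NULL) {
  win <- findMostActiveMinute(movie, searchStart, searchEnd)
  bin <- binarizeWindow(movie, win)
  dec <- smoothAndDeconvolve(bin, iterations = iterations)
  roiset <- identifyRois(dec$projection, nActive = nActive,
                         nInactive = nInactive, diameterPx = diameterPx)
  corr <- roiCorrelationAnalysis(roiset, movie, win)
  list(window = win, projection = dec$projection,
       roiset = corr$roiset, correlations = corr)
}
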