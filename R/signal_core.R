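## Fundamental trace operations shared by every pipeline: dF/F0, binning,
## smoothing, detrending, z-scoring and the two nonlinear fits (one-phase
## exponential, four-parameter logistic).

#' Compute dF/F0 relative to a pre-ligand baseline
#'
#' The sensor response is (F(t) - F0) / F0 with F0 the mean fluorescence over
#' the baseline specification: either an explicit time window, or the n
#' samples immediately preceding an event time (the in vitro convention is
#' the ten time points immediately before ligand addition).
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param baselineWindow numeric length-2 (start, end) in seconds, absolute
#'   trace time; samples with start <= t < end are used.
#' @param nPoints integer, number of samples immediately before
#'   \code{eventTime} to average (used when \code{baselineWindow} is NULL).
#' @param eventTime event (ligand addition) time in seconds; required with
#'   \code{nPoints}.
#' @return a \linkS4class{DffTrace}; values are dimensionless fractions
#'   (multiply by 100 for percent).
#' @examples
#' tr <- FluorescenceTrace(c(rep(2, 10), rep(4, 10)), samplingRate = 1)
#' dff <- computeDff(tr, nPoints = 10, eventTime = 10)
#' tail(traceValues(dff), 1)  # (4 - 2)/2 = 1
#' @export
computeDff <- function(trace, baselineWindow = NULL, nPoints = 10,
                       eventTime = NULL) {
  stopifnot(is(trace, "FluorescenceTrace"))
  tt <- traceTimes(trace)
  v <- traceValues(trace)
  if (!is.null(baselineWindow)) {
    if (length(baselineWindow) != 2L || baselineWindow[1] >= baselineWindow[2])
      stop("'baselineWindow' must be (start, end) with start < end")
    idx <- which(tt >= baselineWindow[1] & tt < baselineWindow[2])
    win <- baselineWindow
  } else {
    if (is.null(eventTime))
      stop("either 'baselineWindow' or 'eventTime' (with 'nPoints') is required")
    before <- which(tt < eventTime)
    if (length(before) < nPoints)
      stop("fewer than ", nPoints, " samples before the event")
    idx <- utils::tail(before, nPoints)
    win <- c(tt[idx[1]], eventTime)
  }
  if (length(idx) == 0L)
    stop("baseline window contains no samples")
  f0 <- mean(v[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean must be positive; got ", format(f0))
  new("DffTrace", values = (v - f0) / f0, samplingRate = samplingRate(trace),
      t0 = trace@t0, annotations = annotations(trace),
      metadata = traceMetadata(trace),
      baselineValue = f0, baselineWindow = as.numeric(win))
}

#' Average a trace into fixed-width time bins
#'
#' Each output sample is the mean of the input samples falling in its bin;
#' a trailing partial bin is dropped. The output sampling rate is
#' 1/\code{binWidth} and the first output sample keeps the input \code{t0}
#' (left bin-edge convention).
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param binWidth bin width in seconds; must be at least one sample period.
#' @return a binned \linkS4class{FluorescenceTrace}.
#' @export
binTrace <- function(trace, binWidth = 0.1) {
  stopifnot(is(trace, "FluorescenceTrace"))
  sr <- samplingRate(trace)
  if (binWidth < 1 / sr - 1e-12)
    stop("'binWidth' must be at least one sample period (", 1 / sr, " s)")
  v <- traceValues(trace)
  n <- length(v)
  nbins <- floor(n / (binWidth * sr) + 1e-9)
  if (nbins < 1L) stop("trace shorter than one bin")
  # bin index of each sample by time from t0 (half-open bins [k*w, (k+1)*w))
  rel <- (seq_len(n) - 1L) / sr
  bi <- floor(rel / binWidth + 1e-9) + 1L
  keep <- bi <= nbins
  means <- as.numeric(tapply(v[keep], bi[keep], mean))
  ann <- annotations(trace)
  tend <- trace@t0 + nbins * binWidth
  if (nrow(ann)) {
    ann <- ann[ann$start < tend, , drop = FALSE]
    ann$end <- pmin(ann$end, tend)
  }
  FluorescenceTrace(means, samplingRate = 1 / binWidth, t0 = trace@t0,
                    annotations = ann, metadata = traceMetadata(trace))
}

#' Remove a linear trend anchored on the first- and last-window medians
#'
#' Fits a straight line through (center of the first \code{anchorWidth}
#' seconds, median of that window) and (center of the last
#' \code{anchorWidth} seconds, its median), and subtracts it. This removes
#' the slow baseline drift of anesthetized photometry recordings while
#' preserving transients in the middle of the window.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param anchorWidth anchor window width in seconds (default 30).
#' @return the detrended \linkS4class{FluorescenceTrace}.
#' @export
detrendLinearMedian <- function(trace, anchorWidth = 30) {
  stopifnot(is(trace, "FluorescenceTrace"))
  dur <- traceDuration(trace)
  if (dur < 2 * anchorWidth)
    stop("trace duration (", dur, " s) must be at least 2 * anchorWidth")
  v <- traceValues(trace)
  tt <- traceTimes(trace)
  rel <- tt - trace@t0
  i1 <- which(rel < anchorWidth)
  i2 <- which(rel >= dur - anchorWidth)
  m1 <- stats::median(v[i1]); m2 <- stats::median(v[i2])
  c1 <- mean(tt[i1]); c2 <- mean(tt[i2])
  slope <- (m2 - m1) / (c2 - c1)
  line <- m1 + slope * (tt - c1)
  FluorescenceTrace(v - line, samplingRate = samplingRate(trace),
                    t0 = trace@t0, annotations = annotations(trace),
                    metadata = traceMetadata(trace))
}

#' z-score a trace against a baseline window
#'
#' z(t) = (x(t) - median(baseline)) / sd(baseline), with the sample (n - 1)
#' standard deviation of the baseline-window values.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param baselineWindow numeric length-2 (start, end), seconds, absolute
#'   trace time; samples with start <= t < end form the baseline.
#' @return a \linkS4class{ZScoredTrace}.
#' @export
zscoreBaseline <- function(trace, baselineWindow) {
  stopifnot(is(trace, "FluorescenceTrace"), length(baselineWindow) == 2L)
  tt <- traceTimes(trace)
  v <- traceValues(trace)
  idx <- which(tt >= baselineWindow[1] & tt < baselineWindow[2])
  if (length(idx) < 2L)
    stop("baseline window must contain at least two samples")
  med <- stats::median(v[idx])
  s <- stats::sd(v[idx])
  if (!is.finite(s) || s <= 0)
    stop("degenerate baseline: standard deviation is zero")
  new("ZScoredTrace", values = (v - med) / s,
      samplingRate = samplingRate(trace), t0 = trace@t0,
      annotations = annotations(trace), metadata = traceMetadata(trace),
      baselineMedian = med, baselineSd = s,
      baselineWindow = as.numeric(baselineWindow))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with a window of \code{windowS}
#' seconds (rounded to an odd number of samples) and polynomial order
#' \code{polyorder}. A single-sample window is the identity.
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param windowS filter length in seconds (published photometry analyses
#'   use 4 s).
#' @param polyorder polynomial order (default 3).
#' @return the smoothed trace, same class and length.
#' @export
savgolSmooth <- function(trace, windowS = 4, polyorder = 3) {
  stopifnot(is(trace, "FluorescenceTrace"))
  sr <- samplingRate(trace)
  n <- max(1L, round(windowS * sr))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(trace)
  if (n <= polyorder)
    stop("window of ", n, " samples must exceed polyorder ", polyorder)
  v <- traceValues(trace)
  if (length(v) < n)
    stop("trace shorter than the smoothing window")
  sm <- signal::sgolayfilt(v, p = polyorder, n = n)
  initialize(trace, values = as.numeric(sm))
}

## data-driven starting values for the exponential fits: the offset from
## the end of the trace nearest the asymptote, the amplitude from the
## start-to-end excursion, tau from the time to 63% of that excursion
.expStart <- function(t, y, direction) {
  n <- length(y)
  k <- max(2L, round(n / 20))
  headM <- mean(y[seq_len(k)])
  tailM <- mean(y[(n - k + 1):n])
  if (direction == "rise") {
    offset <- headM
    amp <- tailM - headM
    icross <- which((y - offset) / ifelse(amp == 0, 1, amp) >= 0.632)
  } else {
    offset <- tailM
    amp <- headM - tailM
    icross <- which((y - offset) / ifelse(amp == 0, 1, amp) <= 0.368)
  }
  tau0 <- if (length(icross)) max(t[icross[1]] - t[1], diff(range(t)) / 200)
          else diff(range(t)) / 3
  list(offset = offset, amplitude = if (amp == 0) diff(range(y)) else amp,
       tau = tau0)
}

#' Fit a one-phase exponential association or decay
#'
#' Rise: y(t) = offset + amplitude (1 - exp(-t/tau)); decay:
#' y(t) = offset + amplitude exp(-t/tau), with t measured from the start of
#' the fitted window. Starting values are taken from the data (offset = first
#' decile, amplitude = range, tau = time to 63\% of range) and tau is bounded
#' in (0, 10 x window duration]. Non-convergence and degenerate (flat) input
#' are reported through the \code{converged} flag, never as an error.
#'
#' @param trace a \linkS4class{FluorescenceTrace}, or a numeric vector with
#'   \code{rateHz} given.
#' @param direction "rise" or "decay".
#' @param rateHz sampling rate in Hz when \code{trace} is a bare numeric
#'   vector.
#' @return a \linkS4class{KineticsFit}.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' y <- 0.2 + 1.5 * (1 - exp(-t / 1.0))
#' fitExpAssociation(FluorescenceTrace(y, 100), "rise")
#' @export
fitExpAssociation <- function(trace, direction = c("rise", "decay"),
                              rateHz = NULL) {
  direction <- match.arg(direction)
  if (is(trace, "FluorescenceTrace")) {
    y <- traceValues(trace)
    sr <- samplingRate(trace)
  } else {
    y <- as.numeric(trace)
    if (is.null(rateHz)) stop("'rateHz' required for a vector")
    sr <- rateHz
  }
  if (length(y) < 10L) stop("at least 10 samples are required")
  if (!all(is.finite(y))) stop("values must be finite")
  t <- (seq_along(y) - 1L) / sr
  dur <- max(t)
  degenerate <- function(r2) new("KineticsFit", tau = NA_real_,
      amplitude = 0, offset = mean(y), rSquared = r2, converged = FALSE,
      direction = direction)
  if (stats::sd(y) == 0) return(degenerate(0))
  st <- .expStart(t, y, direction)
  form <- if (direction == "rise")
    y ~ offset + amplitude * (1 - exp(-t / tau))
  else
    y ~ offset + amplitude * exp(-t / tau)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t = t, y = y),
      start = list(offset = st$offset, amplitude = st$amplitude,
                   tau = st$tau),
      lower = c(-Inf, -Inf, 1e-9), upper = c(Inf, Inf, 10 * dur),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(degenerate(NA_real_))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ss <- sum((y - mean(y))^2)
  r2 <- if (ss > 0) max(0, min(1, 1 - sum(res^2) / ss)) else 0
  conv <- is.finite(cf[["tau"]]) && cf[["tau"]] > 0 &&
    cf[["tau"]] < 10 * dur - 1e-9 && abs(cf[["amplitude"]]) > 0
  new("KineticsFit", tau = unname(cf[["tau"]]),
      amplitude = unname(cf[["amplitude"]]), offset = unname(cf[["offset"]]),
      rSquared = r2, converged = conv, direction = direction)
}

#' Fit a four-parameter logistic (Hill) dose-response curve
#'
#' y = bottom + (top - bottom) / (1 + (ec50/x)^hill), fitted on log10(dose)
#' for numerical stability. Zero doses are mapped to a pseudo-dose two
#' decades below the smallest nonzero dose. With \code{normalize = TRUE}
#' responses are first scaled to [0, 1]. \code{weighting = "relative"}
#' applies 1/y^2 weights, the appropriate scheme when response errors are
#' proportional to the response (as in titration imaging, where bright
#' wells are noisier in absolute terms).
#'
#' @param doses numeric vector of ligand concentrations (mol/L).
#' @param responses numeric vector of responses, same length.
#' @param normalize scale responses to [0, 1] before fitting.
#' @param weighting "none" (ordinary least squares) or "relative"
#'   (1/y^2 weights for multiplicative errors).
#' @return a \linkS4class{DoseResponseFit}.
#' @examples
#' d <- 10^seq(-9, -6, length.out = 8)
#' y <- 1 / (1 + (75e-9 / d))
#' fitParameters(fit4PL(d, y))["ec50"]
#' @export
fit4PL <- function(doses, responses, normalize = FALSE,
                   weighting = c("none", "relative")) {
  weighting <- match.arg(weighting)
  stopifnot(length(doses) == length(responses))
  if (length(unique(doses)) < 4L)
    stop("at least 4 distinct doses are required")
  failed <- function() new("DoseResponseFit", converged = FALSE,
                           rSquared = NA_real_)
  if (stats::sd(responses) == 0) return(failed())
  y <- responses
  if (normalize) {
    rng <- range(y)
    if (diff(rng) == 0) return(failed())
    y <- (y - rng[1]) / diff(rng)
  }
  d <- doses
  if (any(d < 0)) stop("doses must be non-negative")
  if (any(d == 0)) {
    pseudo <- min(d[d > 0]) / 100
    d[d == 0] <- pseudo
  }
  ld <- log10(d)
  hill0 <- if (stats::cor(ld, y) < 0) -1 else 1
  st <- list(bottom = min(y), top = max(y), logEc50 = stats::median(ld),
             hill = hill0)
  w <- if (weighting == "relative")
    1 / pmax(abs(y), 0.05 * max(abs(y)))^2 else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (logEc50 - ld))),
      data = data.frame(ld = ld, y = y), start = st, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  res <- y - stats::predict(fit)
  ss <- sum((y - mean(y))^2)
  r2 <- if (ss > 0) max(0, min(1, 1 - sum(res^2) / ss)) else 0
  ec50 <- 10^cf[["logEc50"]]
  conv <- is.finite(ec50) && ec50 > 0
  new("DoseResponseFit", ec50 = unname(ec50),
      hillSlope = unname(cf[["hill"]]), top = unname(cf[["top"]]),
      bottom = unname(cf[["bottom"]]), rSquared = r2, converged = conv)
}
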