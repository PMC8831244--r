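# Core trace operations: dF/F0, binning, detrending, z-scoring, smoothing
# and the two nonlinear fits.

test_that("computeDff normalizes against the n-point pre-event baseline", {
  # constant trace: identity case
  d0 <- computeDff(constTrace(5), baselineWindow = c(0, 1))
  expect_true(all(traceValues(d0) == 0))
  expect_equal(baselineValue(d0), 5)

  # direct arithmetic: baseline mean 2.0, later sample 3.5 -> 0.75
  tr <- FluorescenceTrace(c(rep(2, 10), 3.5), samplingRate = 1)
  d <- computeDff(tr, nPoints = 10, eventTime = 10)
  expect_equal(traceValues(d)[11], 0.75)

  # ten noisy baseline points averaging exactly 2.0, plateau 20.12 ->
  # dF/F0 = 9.06 (a 906% response)
  base <- c(1.9, 2.1, 1.95, 2.05, 1.98, 2.02, 1.9, 2.1, 2.0, 2.0)
  stopifnot(mean(base) == 2)
  tr <- FluorescenceTrace(c(base, rep(20.12, 20)), samplingRate = 1)
  d <- computeDff(tr, nPoints = 10, eventTime = 10)
  expect_equal(traceValues(d)[11], 9.06)
})

test_that("computeDff is scale invariant and rejects bad baselines", {
  set.seed(42)
  v <- runif(50, 1, 3)
  tr1 <- FluorescenceTrace(v, samplingRate = 5)
  for (c0 in c(0.5, 2, 117)) {
    tr2 <- FluorescenceTrace(c0 * v, samplingRate = 5)
    expect_equal(traceValues(computeDff(tr2, baselineWindow = c(0, 2))),
                 traceValues(computeDff(tr1, baselineWindow = c(0, 2))))
  }
  neg <- FluorescenceTrace(c(rep(-1, 10), rep(2, 10)), samplingRate = 1)
  expect_error(computeDff(neg, baselineWindow = c(0, 5)), "positive")
  expect_error(computeDff(tr1, baselineWindow = c(100, 101)), "no samples")
})

test_that("binTrace matches a brute-force binner and drops partial bins", {
  expect_equal(traceValues(binTrace(constTrace(3, 400, 400), 0.1)),
               rep(3, 10))

  set.seed(7)
  v <- rnorm(800)
  tr <- FluorescenceTrace(v, samplingRate = 400)
  got <- traceValues(binTrace(tr, 0.1))
  want <- vapply(seq_len(20), function(k)
    mean(v[((k - 1) * 40 + 1):(k * 40)]), numeric(1))
  expect_equal(got, want)

  # 401 samples at 400 Hz -> 10 full bins, last sample dropped
  tr <- FluorescenceTrace(rnorm(401), samplingRate = 400)
  expect_length(traceValues(binTrace(tr, 0.1)), 10)

  # total signal conserved over the used samples
  b <- binTrace(FluorescenceTrace(v, samplingRate = 400), 0.1)
  expect_equal(sum(traceValues(b)) * 40, sum(v))

  expect_error(binTrace(tr, 1 / 800), "sample period")
})

test_that("detrendLinearMedian removes a line and preserves a pulse", {
  rate <- 10
  t <- seq(0, 99.9, by = 0.1)
  line <- 2 + 0.05 * t
  tr <- FluorescenceTrace(line, samplingRate = rate)
  res <- traceValues(detrendLinearMedian(tr, anchorWidth = 30))
  expect_lt(max(abs(res)), 1e-10)

  pulse <- ifelse(t > 45 & t < 55, 3, 0)
  tr2 <- FluorescenceTrace(line + pulse, samplingRate = rate)
  res2 <- traceValues(detrendLinearMedian(tr2, anchorWidth = 30))
  expect_equal(res2, pulse)          # oracle: subtract the known line

  resC <- detrendLinearMedian(constTrace(4, 1000, rate), anchorWidth = 30)
  expect_true(all(abs(traceValues(resC)) < 1e-12))

  expect_error(detrendLinearMedian(constTrace(1, 100, rate), 30),
               "duration")
})

test_that("zscoreBaseline uses the baseline median and sample s.d.", {
  # baseline {0,0,1,1}: median 0.5, sample s.d. 0.57735; sample 1.5 -> 1.732
  tr <- FluorescenceTrace(c(0, 0, 1, 1, 1.5), samplingRate = 1)
  z <- zscoreBaseline(tr, baselineWindow = c(0, 4))
  expect_equal(traceValues(z)[5], 1.7320508, tolerance = 1e-6)
  expect_equal(unname(baselineStats(z)["median"]), 0.5)

  # sample equal to the baseline median maps to zero
  tr2 <- FluorescenceTrace(c(0, 0, 1, 1, 0.5), samplingRate = 1)
  expect_equal(traceValues(zscoreBaseline(tr2, c(0, 4)))[5], 0)

  expect_error(zscoreBaseline(constTrace(2, 20, 1), c(0, 10)),
               "degenerate")

  # invariance under positive affine transforms of the input
  set.seed(3)
  v <- rnorm(100)
  tr3 <- FluorescenceTrace(v, samplingRate = 10)
  z1 <- traceValues(zscoreBaseline(tr3, c(0, 5)))
  for (ab in list(c(2, 1), c(0.3, -4))) {
    tr4 <- FluorescenceTrace(ab[1] * v + ab[2], samplingRate = 10)
    expect_equal(traceValues(zscoreBaseline(tr4, c(0, 5))), z1)
  }
})

test_that("savgolSmooth preserves low-order polynomials and denoises", {
  rate <- 10
  t <- seq(0, 9.9, by = 0.1)
  poly <- 1 + 2 * t - 0.3 * t^2 + 0.01 * t^3
  sm <- savgolSmooth(FluorescenceTrace(poly, samplingRate = rate),
                     windowS = 2.1, polyorder = 3)
  interior <- 12:88
  expect_equal(traceValues(sm)[interior], poly[interior], tolerance = 1e-9)

  set.seed(11)
  noisy <- sin(t) + rnorm(length(t), 0, 0.3)
  smn <- savgolSmooth(FluorescenceTrace(noisy, samplingRate = rate), 2.1, 3)
  expect_lt(var(traceValues(smn) - sin(t)), var(noisy - sin(t)))

  # one-sample window is the identity
  tr <- FluorescenceTrace(noisy, samplingRate = rate)
  expect_equal(traceValues(savgolSmooth(tr, windowS = 0.05, polyorder = 0)),
               noisy)
  expect_error(savgolSmooth(tr, windowS = 0.3, polyorder = 5), "polyorder")
})

test_that("fitExpAssociation recovers noiseless time constants exactly", {
  t <- seq(0, 5, by = 0.01)
  y <- 0.5 + 2 * (1 - exp(-t / 1.0))
  f <- fitExpAssociation(y, "rise", rateHz = 100)
  expect_true(isConverged(f))
  expect_equal(unname(fitParameters(f)["tau"]), 1.0, tolerance = 1e-6)

  # 550 Hz recording with the sensor's sub-second activation constant
  t2 <- seq(0, 5, by = 1 / 550)
  y2 <- 10 + 90 * (1 - exp(-t2 / 0.596))
  f2 <- fitExpAssociation(y2, "rise", rateHz = 550)
  expect_equal(unname(fitParameters(f2)["tau"]), 0.596, tolerance = 1e-6)

  yd <- 1 + 3 * exp(-t / 0.8)
  fd <- fitExpAssociation(yd, "decay", rateHz = 100)
  expect_equal(unname(fitParameters(fd)["tau"]), 0.8, tolerance = 1e-6)

  flat <- fitExpAssociation(rep(2, 100), "rise", rateHz = 10)
  expect_false(isConverged(flat))
  expect_equal(unname(fitParameters(flat)["amplitude"]), 0)

  expect_error(fitExpAssociation(1:5, "rise", rateHz = 10), "10 samples")
})

test_that("tau recovery is accurate over the usable range and under noise", {
  # noiseless: relative error < 1e-4 for tau/duration in [0.02, 0.5]
  dur <- 10; rate <- 50
  t <- seq(0, dur, by = 1 / rate)
  for (frac in c(0.02, 0.1, 0.3, 0.5)) {
    tau <- frac * dur
    y <- 1 + 5 * (1 - exp(-t / tau))
    f <- fitExpAssociation(y, "rise", rateHz = rate)
    expect_lt(abs(fitParameters(f)["tau"] - tau) / tau, 1e-4)
  }
  # 5% amplitude noise: median relative error < 5% over 100 replicates
  tau <- 1.5
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 1 + 5 * (1 - exp(-t / tau)) + rnorm(length(t), 0, 0.25)
    f <- fitExpAssociation(y, "rise", rateHz = rate)
    abs(fitParameters(f)[["tau"]] - tau) / tau
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("fit4PL recovers logistic parameters and flags degenerate input", {
  d <- 75e-9 * 10^seq(-2, 2, length.out = 8)
  y <- 0.1 + 0.9 / (1 + (75e-9 / d)^1)
  f <- fit4PL(d, y)
  expect_true(isConverged(f))
  p <- fitParameters(f)
  expect_equal(unname(p["ec50"]), 75e-9, tolerance = 1e-3)
  expect_equal(unname(p["hillSlope"]), 1, tolerance = 1e-3)
  expect_equal(unname(p["top"]), 1.0, tolerance = 1e-3)
  expect_equal(unname(p["bottom"]), 0.1, tolerance = 1e-3)

  # monotone-decreasing responses fit with a negative Hill slope
  fdec <- fit4PL(d, 1 - y)
  expect_lt(fitParameters(fdec)["hillSlope"], 0)

  expect_error(fit4PL(c(1, 1, 2, 2) * 1e-9, c(0, 0, 1, 1)), "4 distinct")
  expect_false(isConverged(fit4PL(d, rep(0.5, 8))))

  # zero dose is mapped to a pseudo-dose, not an error
  f0 <- fit4PL(c(0, d), c(0.1, y))
  expect_true(isConverged(f0))
})

test_that("EC50 is recovered within 10% at 10% response noise", {
  med <- median(vapply(1:100, function(s) {
    dr <- genDoseResponse(s)
    fitParameters(fit4PL(dr$doses, dr$responses))[["ec50"]]
  }, numeric(1)))
  expect_lt(abs(med - 75e-9) / 75e-9, 0.10)
})
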