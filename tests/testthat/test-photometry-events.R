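# Trial- and event-level photometry: stimulation trials, behavioural
# events and sleep-state transitions.

test_that("analyzeStimTrial finds the laser-on peak and survives trends", {
  stim <- StimTrain(onset = 60)
  tr <- genPhotometry(1)
  res <- analyzeStimTrial(tr, stim)
  expect_s4_class(res, "StimResponse")
  # peak must fall inside the laser-on interval and be large for a strong
  # synthetic response
  z <- res@zTrace
  tpk <- traceTimes(z)[which.max(traceValues(z) *
    (traceTimes(z) >= 60 & traceTimes(z) <= 90))]
  expect_gte(tpk, 60); expect_lte(tpk, 90)
  expect_gt(res@peakZ, 20)
  expect_false(res@excluded)

  # adding any linear trend leaves the result unchanged (detrend property)
  tt <- traceTimes(tr)
  for (sl in c(-0.5, 0.8)) {
    tr2 <- FluorescenceTrace(traceValues(tr) + sl * tt,
                             samplingRate = samplingRate(tr))
    res2 <- analyzeStimTrial(tr2, stim)
    # median-based anchors make trend removal exact only up to the
    # baseline medians' interaction with noise; agreement is still tight
    expect_equal(res2@peakZ, res@peakZ, tolerance = 1e-2)
  }

  expect_error(analyzeStimTrial(constTrace(1, 100, 10), stim), "cover")
})

test_that("flat trials give zero peak and degenerate, excluded fits", {
  flat <- FluorescenceTrace(rep(2, 180 * 400), samplingRate = 400)
  res <- analyzeStimTrial(flat, StimTrain(onset = 60))
  expect_equal(res@peakZ, 0)
  expect_false(isConverged(res@riseFit))
  expect_false(isConverged(res@decayFit))
  expect_true(res@excluded)
})

test_that("stimulus pipeline recovers the published 20 Hz kinetics", {
  # single noise-free trial: bias of the bin/smooth/detrend/fit chain alone
  tr <- genPhotometry(1, noiseSd = 0)
  res <- analyzeStimTrial(tr, StimTrain(onset = 60))
  expect_equal(res@riseFit@tau, 6.77, tolerance = 0.1)
  expect_equal(res@decayFit@tau, 16.31, tolerance = 0.1)
})

test_that("peak z grows monotonically with response amplitude", {
  # amplitudes mimicking the 1/5/10/20 Hz frequency series
  peaks <- vapply(c(1, 4, 8, 12), function(a) {
    tr <- genPhotometry(5, amplitude = a, noiseSd = 0.5)
    analyzeStimTrial(tr, StimTrain(onset = 60))@peakZ
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("eventLockedComparison measures pre vs event means", {
  rate <- 20
  t <- seq(0, 39.95, by = 1 / rate)
  set.seed(8)
  base <- 0.02 * rnorm(length(t))
  step <- base + ifelse(t >= 20, 0.1, 0)
  dff <- new("DffTrace", values = step, samplingRate = rate, t0 = 0,
             baselineValue = 1, baselineWindow = c(0, 1))
  res <- eventLockedComparison(dff, eventOnset = 20)
  expect_equal(res$eventMean - res$preMean, 0.1, tolerance = 0.02)
  expect_equal(sd(traceValues(res$normalizedTrace)[t >= 15 & t < 20]), 1,
               tolerance = 1e-9)

  con <- new("DffTrace", values = base, samplingRate = rate, t0 = 0,
             baselineValue = 1, baselineWindow = c(0, 1))
  r2 <- eventLockedComparison(con, eventOnset = 20)
  expect_equal(r2$preMean, mean(base[t >= 15 & t < 20]))

  expect_error(eventLockedComparison(dff, eventOnset = 2), "not covered")
})

test_that("stateTransitionDeltas recovers square-wave REM drops exactly", {
  # noise-free generator trace: dF/F0 drops by 0.2 at each NREM->REM
  states <- c(rep("wake", 40), rep("NREM", 60), rep("REM", 40),
              rep("wake", 40), rep("NREM", 60), rep("REM", 40),
              rep("wake", 20))
  hg <- genHypnogram(1, states = states, noiseSd = 0, remDrop = 0.2)
  d <- stateTransitionDeltas(hg$trace, hg$hypnogram, "NREM->REM")
  expect_equal(nrow(d), 2)
  expect_equal(d$delta, c(0.2, 0.2))
  dw <- stateTransitionDeltas(hg$trace, hg$hypnogram, "REM->wake")
  expect_equal(dw$delta, c(0.2, 0.2))

  # constant trace: all deltas zero
  hgc <- genHypnogram(1, states = states, noiseSd = 0, remDrop = 0)
  expect_equal(stateTransitionDeltas(hgc$trace, hgc$hypnogram,
                                     "NREM->REM")$delta, c(0, 0))

  # absent transition type: empty result, no error
  expect_equal(nrow(stateTransitionDeltas(hg$trace, hg$hypnogram,
                                          "NREM->wake")), 0)

  # transition too close to the recording edge is skipped with a warning
  early <- c(rep("NREM", 5), rep("REM", 40), rep("wake", 100))
  hge <- genHypnogram(1, states = early, noiseSd = 0)
  expect_warning(de <- stateTransitionDeltas(hge$trace, hge$hypnogram,
                                             "NREM->REM"), "skipped")
  expect_equal(nrow(de), 0)
})

test_that("transition deltas scale linearly with signal attenuation", {
  # suvorexant-like attenuation: scaling the trace scales the deltas
  states <- c(rep("wake", 40), rep("NREM", 60), rep("REM", 40),
              rep("wake", 40))
  hg <- genHypnogram(3, states = states, noiseSd = 0.005)
  d1 <- stateTransitionDeltas(hg$trace, hg$hypnogram, "NREM->REM")$delta
  s <- 0.4
  tr2 <- new("DffTrace", values = s * traceValues(hg$trace),
             samplingRate = samplingRate(hg$trace), t0 = 0,
             baselineValue = 1, baselineWindow = c(0, 1))
  d2 <- stateTransitionDeltas(tr2, hg$hypnogram, "NREM->REM")$delta
  expect_equal(d2, s * d1)
})

test_that("stateMeanDff matches brute-force epoch masking", {
  states <- c(rep("wake", 30), rep("NREM", 30), rep("REM", 30))
  hyp <- Hypnogram(states)
  rate <- 10
  set.seed(4)
  v <- rnorm(900)
  dff <- new("DffTrace", values = v, samplingRate = rate, t0 = 0,
             baselineValue = 1, baselineWindow = c(0, 1))
  got <- stateMeanDff(dff, hyp)
  t <- traceTimes(dff)
  want <- vapply(c(wake = "wake", NREM = "NREM", REM = "REM"), function(s)
    mean(v[states[floor(t) + 1] == s]), numeric(1))
  expect_equal(got, want)

  # indicator trace: wake mean 1, others 0
  ind <- new("DffTrace", values = as.numeric(states[floor(t) + 1] == "wake"),
             samplingRate = rate, t0 = 0, baselineValue = 1,
             baselineWindow = c(0, 1))
  expect_equal(unname(stateMeanDff(ind, hyp)), c(1, 0, 0))

  # absent state flagged
  expect_warning(m <- stateMeanDff(dff, Hypnogram(rep("REM", 90))),
                 "absent")
  expect_true(is.na(m["wake"]) && is.na(m["NREM"]))
})
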