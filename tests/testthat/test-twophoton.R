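# Two-photon pipeline: FOV dF/F0, most-active-minute, binarization,
# smoothing + deconvolution, ROI identification and correlations.

test_that("fovDffTrace uses the anesthetized-period median baseline", {
  # frame rate chosen so one minute = 3 frames; first-minute means
  # {1,1,2} -> median 1; later frame mean 1.5 -> dF/F0 = 0.5
  mv <- frameValueMovie(c(1, 1, 2, 1.5), frameRate = 0.05)
  d <- fovDffTrace(mv)
  expect_equal(traceValues(d), c(0, 0, 1, 0.5))
  expect_equal(baselineValue(d), 1)

  con <- frameValueMovie(rep(3, 5), frameRate = 0.05)
  expect_true(all(traceValues(fovDffTrace(con)) == 0))

  # monotone ramp: last-minute mean dF/F0 exceeds first-minute mean
  ramp <- frameValueMovie(seq(1, 2, length.out = 12), frameRate = 0.05)
  dr <- traceValues(fovDffTrace(ramp))
  expect_gt(mean(tail(dr, 3)), mean(head(dr, 3)))

  expect_error(fovDffTrace(frameValueMovie(c(1, 2), frameRate = 0.05)),
               "one minute")
})

test_that("firstLastMinuteDelta measures the wake-up rise", {
  flat <- fovDffTrace(frameValueMovie(rep(2, 10), frameRate = 0.05))
  expect_equal(firstLastMinuteDelta(flat), 0)

  # step of +0.3 (in dF/F0 units) at the midpoint
  vals <- c(rep(1, 6), rep(1.3, 6))
  d <- fovDffTrace(frameValueMovie(vals, frameRate = 0.05))
  expect_equal(firstLastMinuteDelta(d), 0.3)

  expect_error(firstLastMinuteDelta(
    fovDffTrace(frameValueMovie(rep(1, 4), frameRate = 0.05))), "two minutes")
})

test_that("findMostActiveMinute maximizes mean spatial s.d.", {
  fr <- 0.1                          # one minute = 6 frames
  set.seed(21)
  nT <- 40
  frames <- array(rnorm(nT * 8 * 8, 10, 0.01), c(nT, 8, 8))
  # contrast burst in frames 25-30
  frames[25:30, , ] <- pmax(frames[25:30, , ] +
    array(rnorm(6 * 64, 0, 3), c(6, 8, 8)), 0)
  mv <- ImagingMovie(frames, frameRate = fr)
  w <- findMostActiveMinute(mv, searchStart = 13, searchEnd = 36)
  wf <- windowFrames(w)
  expect_true(wf["start"] <= 25 && wf["end"] >= 30)

  # search period of exactly one minute returns that window
  w1 <- findMostActiveMinute(mv, searchStart = 7, searchEnd = 12)
  expect_equal(unname(windowFrames(w1)), c(7, 12))

  # constant movie: every window ties, earliest returned
  conM <- ImagingMovie(array(1, c(nT, 4, 4)), frameRate = fr)
  wc <- findMostActiveMinute(conM, searchStart = 5, searchEnd = 20)
  expect_equal(unname(windowFrames(wc)["start"]), 5)

  expect_error(findMostActiveMinute(mv, searchStart = 10, searchEnd = 12),
               "one minute")
})

test_that("binarizeWindow equals the hand and brute-force oracles", {
  # constant movie: strict inequality keeps everything 0
  conM <- ImagingMovie(array(2, c(10, 3, 3)), frameRate = 0.1)
  expect_true(all(movieFrames(binarizeWindow(conM, c(1, 10))) == 0))

  # single pixel {1,1,1,1,10}: median 1, sample s.d. 4.0249 -> only the
  # last frame exceeds the threshold
  px <- ImagingMovie(array(c(1, 1, 1, 1, 10), c(5, 1, 1)), frameRate = 0.1)
  expect_equal(as.numeric(movieFrames(binarizeWindow(px, c(1, 5)))),
               c(0, 0, 0, 0, 1))

  # random movie equals a per-pixel loop exactly
  set.seed(33)
  fr <- array(rpois(30 * 6 * 6, 20), c(30, 6, 6))
  mv <- ImagingMovie(fr, frameRate = 0.5)
  got <- movieFrames(binarizeWindow(mv, c(6, 25)))
  want <- array(0, c(20, 6, 6))
  for (i in 1:6) for (j in 1:6) {
    v <- fr[6:25, i, j]
    want[, i, j] <- as.numeric(v > median(v) + sd(v))
  }
  expect_identical(got, want)
})

test_that("binarization is invariant to affine intensity rescaling", {
  set.seed(44)
  fr <- array(rpois(30 * 5 * 5, 15), c(30, 5, 5))
  mv1 <- ImagingMovie(fr, frameRate = 0.5)
  b1 <- movieFrames(binarizeWindow(mv1, c(1, 30)))
  for (ab in list(c(3, 7), c(0.25, 1))) {
    mv2 <- ImagingMovie(ab[1] * fr + ab[2], frameRate = 0.5)
    expect_identical(movieFrames(binarizeWindow(mv2, c(1, 30))), b1)
  }
})

test_that("smoothAndDeconvolve has the expected fixed points and symmetry", {
  mkBin <- function(arr) new("BinarizedMovie", frames = arr,
                             window = c(1, dim(arr)[1]))
  z <- mkBin(array(0, c(3, 50, 50)))
  outz <- smoothAndDeconvolve(z, psfSize = 21, psfSigma = 5)
  expect_true(all(outz$projection == 0))

  # uniform field is a Richardson-Lucy fixed point (circular boundary)
  u <- mkBin(array(1, c(2, 50, 50)))
  outu <- smoothAndDeconvolve(u, psfSize = 21, psfSigma = 5, iterations = 1)
  expect_equal(as.numeric(outu$projection), rep(1, 2500), tolerance = 1e-8)

  # a single symmetric blob keeps its center after deconvolution
  fr <- array(0, c(4, 61, 61))
  for (i in 1:4) fr[i, 26:36, 26:36] <- 1
  outb <- smoothAndDeconvolve(mkBin(fr), psfSize = 21, psfSigma = 5)
  pk <- which(outb$projection == max(outb$projection), arr.ind = TRUE)
  expect_true(any(abs(pk[, 1] - 31) <= 1 & abs(pk[, 2] - 31) <= 1))

  expect_error(smoothAndDeconvolve(mkBin(array(0, c(2, 20, 20)))),
               "larger than the frame")
})

test_that("identifyRois places class-banded, non-overlapping circles", {
  # 12 bright gaussian blobs on a smooth dim background (projections are
  # smooth after deconvolution); brightest 10 get the active ROIs
  H <- 120
  rows <- matrix(seq_len(H), H, H); cols <- t(rows)
  proj <- 1 + 0.002 * rows + 0.001 * cols
  ctr <- expand.grid(r = c(15, 45, 75, 105), c = c(20, 60, 100))
  amp <- seq(2, 4.2, length.out = 12)
  for (k in 1:12)
    proj <- proj + amp[k] * exp(-((rows - ctr$r[k])^2 +
                                  (cols - ctr$c[k])^2) / (2 * 16))
  rs <- identifyRois(proj)
  tab <- roiTable(rs)
  expect_equal(nrow(tab), 20)
  expect_equal(sum(tab$class == "active"), 10)
  act <- tab[tab$class == "active", ]
  # every active center sits on one of the 10 brightest blobs
  top10 <- ctr[order(amp, decreasing = TRUE)[1:10], ]
  hit <- vapply(seq_len(nrow(act)), function(i)
    min(sqrt((act$row[i] - top10$r)^2 + (act$col[i] - top10$c)^2)),
    numeric(1))
  expect_true(all(hit < 6))
  # no two ROIs overlap (centers farther apart than the diameter allows)
  dd <- as.matrix(dist(tab[, c("row", "col")]))
  diag(dd) <- Inf
  expect_true(all(dd > 6))
})

test_that("ROIs never include sub-5th-percentile (vessel) pixels", {
  H <- 80
  rows <- matrix(seq_len(H), H, H); cols <- t(rows)
  proj <- 1 + 0.01 * rows + 0.012 * cols       # smooth projection
  proj[, 38:41] <- 0                            # dark vessel stripe
  rs <- suppressWarnings(identifyRois(proj, nActive = 6, nInactive = 6))
  tab <- roiTable(rs)
  expect_gt(nrow(tab), 6)
  p5 <- roiPercentiles(rs)["p5"]
  offs <- expand.grid(dr = -6:6, dc = -6:6)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 5.5^2, ]
  for (k in seq_len(nrow(tab))) {
    vals <- proj[cbind(tab$row[k] + offs$dr, tab$col[k] + offs$dc)]
    expect_true(all(vals >= p5))
    # no ROI pixel falls in the excluded stripe columns
    expect_false(any((tab$col[k] + offs$dc) %in% 38:41))
  }
})

test_that("roiCorrelationAnalysis separates shared-source from noise ROIs", {
  # two ROI circles driven by one latent course + noise, two pure noise
  set.seed(66)
  H <- 40; nT <- 120
  lat <- rnorm(nT)
  fr <- array(rnorm(nT * H * H, 100, 1), c(nT, H, H))
  add <- function(fr, r0, c0, course) {
    for (i in seq_len(nT)) fr[i, (r0 - 5):(r0 + 5), (c0 - 5):(c0 + 5)] <-
        fr[i, (r0 - 5):(r0 + 5), (c0 - 5):(c0 + 5)] + 10 * course[i]
    fr
  }
  fr <- add(fr, 10, 10, lat); fr <- add(fr, 10, 30, lat)
  mv <- ImagingMovie(fr, frameRate = 2)
  rois <- data.frame(row = c(10, 10, 30, 30), col = c(10, 30, 10, 30),
                     radius = 6, class = c("active", "active",
                                           "inactive", "inactive"))
  rs <- new("RoiSet", rois = rois, traces = matrix(0, 0, 0),
            projection = matrix(0, H, H),
            percentiles = c(p5 = 0, p69 = 0, p70 = 0))
  res <- roiCorrelationAnalysis(rs, mv, c(1, nT))
  expect_equal(dim(res$matrix), c(4, 4))
  expect_equal(unname(diag(res$matrix)), rep(1, 4))
  expect_true(isSymmetric(res$matrix))
  expect_gt(res$meanActiveR, 0.9)
  expect_lt(abs(res$meanInactiveR), 0.3)

  # identical traces correlate at exactly 1
  rois2 <- rois; rois2$row <- 10; rois2$col <- c(10, 10, 30, 30)
  rs2 <- new("RoiSet", rois = rois2, traces = matrix(0, 0, 0),
             projection = matrix(0, H, H),
             percentiles = c(p5 = 0, p69 = 0, p70 = 0))
  res2 <- roiCorrelationAnalysis(rs2, mv, c(1, nT))
  expect_equal(res2$matrix[1, 2], 1)
})

test_that("the full pipeline recovers hotspots on a generator movie", {
  mv <- smallHotspotMovie(7)
  p <- twoPhotonRoiPipeline(mv, nActive = 5, nInactive = 5)
  tab <- roiTable(p$roiset)
  expect_equal(nrow(tab), 10)
  gt <- movieMetadata(mv)$groundTruth
  act <- tab[tab$class == "active", ]
  onHot <- vapply(seq_len(nrow(act)), function(i)
    gt$hotspotMask[act$row[i], act$col[i]] == 1, logical(1))
  expect_gte(sum(onHot), 4)          # at least 4 of 5 on true hotspots
  expect_gt(p$correlations$meanActiveR, p$correlations$meanInactiveR)
})
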