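# Broadband signal chain.

fs <- 30000

test_that("common average referencing nulls the cross-channel mean", {
  expect_equal(commonAverageReference(matrix(c(1, 2, 3), 3L, 1L))[, 1L],
               c(-1, 0, 1))
  same <- matrix(5, 4L, 100L)
  expect_true(all(commonAverageReference(same) == 0))
  set.seed(1)
  seg <- matrix(rnorm(4000), 4L, 1000L)
  expect_lt(max(abs(colMeans(commonAverageReference(seg)))), 1e-9)
  expect_error(commonAverageReference(matrix(1, 1L, 10L)), "2 channels")
})

test_that("spike-band filter kills DC, passes 1 kHz, keeps spikes", {
  cfg <- signalConfig()
  n <- fs  # 1 s
  warm <- 3000L
  # DC
  dc <- matrix(100, 1L, n)
  out <- spikeBandFilter(dc, cfg)
  expect_lt(max(abs(out[1L, warm:n])), 1)
  # 100 Hz: attenuated at least 40 dB (amplitude factor 100)
  t <- (seq_len(n) - 1L) / fs
  lo <- matrix(sin(2 * pi * 100 * t), 1L)
  outLo <- spikeBandFilter(lo, cfg)
  expect_lt(max(abs(outLo[1L, warm:n])), 0.01)
  # 1 kHz: amplitude preserved within 10%
  hi <- matrix(sin(2 * pi * 1000 * t), 1L)
  outHi <- spikeBandFilter(hi, cfg)
  expect_gt(max(abs(outHi[1L, warm:n])), 0.9)
  expect_lt(max(abs(outHi[1L, warm:n])), 1.1)
  # injected biphasic spike on a flat background: peak within 20%
  seg <- matrix(0, 1L, n)
  tmpl <- bcisim:::spikeTemplate() * 120
  seg[1L, 15000L + seq_along(tmpl)] <- tmpl
  outSp <- spikeBandFilter(seg, cfg)
  expect_lt(abs(min(outSp[1L, ]) - min(tmpl)) / abs(min(tmpl)), 0.2)
  expect_error(spikeBandFilter(matrix(0, 1L, 100L), cfg), "warm-up")
})

test_that("threshold detector implements 1-ms presence semantics", {
  flat <- matrix(0, 2L, fs)
  expect_true(all(detectThresholdCrossings(flat, c(-50, -50)) == 0L))
  # one transient inside one window
  seg <- matrix(0, 1L, 3000L)
  seg[1L, 75:80] <- -120
  win <- detectThresholdCrossings(seg, -50)
  expect_identical(sum(win), 1L)
  expect_identical(which(win[1L, ] == 1L), 3L)   # samples 61-90
  expect_error(detectThresholdCrossings(seg, 50), "negative")
})

test_that("false-crossing rate on pure noise matches the Gaussian tail", {
  set.seed(2)
  rms <- 10
  seg <- matrix(rnorm(60 * fs, 0, rms), 1L)
  th <- computeRmsThreshold(seg, -4.5)
  win <- detectThresholdCrossings(seg, th)
  pWindow <- mean(win)
  # analytic per-window bound: 1 - (1 - p1)^30, p1 = P(x < -4.5 sd)
  p1 <- pnorm(-4.5) * 30
  expect_gt(pWindow, p1 / 2)
  expect_lt(pWindow, p1 * 2)
})

test_that("RMS thresholds follow the -4.5 x RMS rule", {
  set.seed(3)
  unitNoise <- matrix(rnorm(2 * fs), 2L)
  th <- computeRmsThreshold(unitNoise, -4.5)
  expect_equal(th, c(-4.5, -4.5), tolerance = 0.02)
  expect_equal(computeRmsThreshold(2 * unitNoise, -4.5), 2 * th,
               tolerance = 1e-12)
  noisy <- matrix(rnorm(10 * fs, 0, 12), 1L)
  th12 <- computeRmsThreshold(noisy, -4.5)
  expect_lt(abs(th12 - (-54)), 0.5)
  expect_warning(computeRmsThreshold(rbind(noisy, 0), -4.5),
                 "zero-variance")
})

test_that("HF-LFP band power matches analytic sinusoid power", {
  cfg <- signalConfig()
  t <- (seq_len(fs) - 1L) / fs
  in300 <- matrix(sin(2 * pi * 300 * t), 1L)
  p300 <- hfLfpPower(in300, cfg)
  # skip warm-up bins, then power ~ 0.5 within 5%
  expect_equal(mean(p300[1L, 10:60]), 0.5, tolerance = 0.05 * 0.5)
  in1k <- matrix(sin(2 * pi * 1000 * t), 1L)
  p1k <- hfLfpPower(in1k, cfg)
  expect_lt(mean(p1k[1L, 10:60]), 0.05 * mean(p300[1L, 10:60]))
  expect_true(all(hfLfpPower(matrix(0, 1L, fs), cfg) == 0))
  bad <- signalConfig()
  bad@hfBand <- c(150, 20000)
  expect_error(hfLfpPower(in300, bad), "Nyquist")
})

test_that("baseline estimation averages the rest period", {
  const <- binnedFeatures(matrix(5L, 2L, 2000L), matrix(5, 2L, 2000L))
  expect_true(all(estimateBaseline(const) == 5))
  set.seed(4)
  pois <- binnedFeatures(matrix(rpois(2 * 2000L, 4), 2L),
                         matrix(1, 2L, 2000L))
  b <- estimateBaseline(pois)[1:2]
  expect_true(all(b > 3.7 & b < 4.3))
  short <- binnedFeatures(matrix(1L, 2L, 10L), matrix(1, 2L, 10L))
  expect_warning(estimateBaseline(short), "rest period")
  # drifting stream: successive block baselines move with the drift
  p <- makeParticipant(nChannels = 6L, driftSigma = 0.08,
                       driftTheta = 0.001, baselineRate = 6, seed = 5L)
  set.seed(6)
  path <- bcisim:::driftPath(p, 6000L)
  enc <- bcisim:::encodeBins(p, matrix(0, 2L, 6000L), rep(FALSE, 6000L),
                             path)
  b1 <- rowMeans(enc$counts[, 1:2000])
  b2 <- rowMeans(enc$counts[, 4001:6000])
  d1 <- rowMeans(path[, 1:2000]); d2 <- rowMeans(path[, 4001:6000])
  big <- abs(d2 - d1) > 0.3        # channels with a clear drift change
  expect_gt(mean(sign(b2 - b1)[big] == sign(d2 - d1)[big]), 0.9)
})

test_that("noise-free spikes survive the whole chain exactly", {
  set.seed(7)
  counts <- matrix(rpois(3L * 80L, 2), 3L, 80L)
  seg <- synthesizeBroadband(counts, noiseRms = 0, seed = 8L)
  # CAR distorts with 3 channels carrying spikes; add quiet channels
  quiet <- matrix(0, 5L, ncol(seg))
  full <- rbind(seg, quiet)
  bf <- extractFeatures(full, signalConfig(spikeThreshold = -50))
  got <- featureMatrix(bf)[featureFamily(bf) == "spike", ][1:3, ]
  want <- pmin(counts, 15L)
  expect_gte(mean(got == want), 0.97)   # rare window-straddling shifts
  expect_equal(sum(got), sum(want), tolerance = 2)
  # common-mode sinusoid is removed by CAR
  cm <- synthesizeBroadband(matrix(0L, 4L, 10L), commonModeAmp = 80,
                            seed = 9L)
  expect_lt(max(abs(commonAverageReference(cm))), 1e-9)
  expect_error(synthesizeBroadband(matrix(0L, 2L, 10L), fs = 10000),
               "30000")
})

test_that("1-ms detections sum exactly into 15-ms bins", {
  set.seed(10)
  counts <- matrix(rpois(2L * 40L, 3), 2L, 40L)
  seg <- synthesizeBroadband(rbind(counts, matrix(0L, 2L, 40L)),
                             noiseRms = 0, seed = 11L)
  cfg <- signalConfig(spikeThreshold = -50)
  ref <- commonAverageReference(seg)
  sb <- spikeBandFilter(ref, cfg)
  win <- detectThresholdCrossings(sb, rep(-50, 4L))
  bf <- extractFeatures(seg, cfg)
  binned <- featureMatrix(bf)[featureFamily(bf) == "spike", ]
  for (b in seq_len(ncol(binned))) {
    idx <- ((b - 1L) * 15L + 1L):(b * 15L)
    expect_identical(as.integer(rowSums(win[, idx])), as.integer(binned[, b]))
  }
})
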