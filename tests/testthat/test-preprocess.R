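test_that("detectTriggers finds injected spikes and collapses doublets", {
  fs <- 2400
  emg <- rnorm(10 * fs, 0, 1)
  spikes <- c(2 * fs, 4 * fs, 7 * fs)
  emg[spikes] <- 500
  expect_identical(detectTriggers(emg, fs), as.integer(spikes))

  # doublet 1 ms apart collapses to one trigger (refractory = 0.5/0.6 s)
  emg2 <- rnorm(10 * fs, 0, 1)
  emg2[c(3 * fs, 3 * fs + round(0.001 * fs))] <- 500
  expect_identical(detectTriggers(emg2, fs), as.integer(3 * fs))

  expect_error(detectTriggers(rep(0, 10 * fs), fs), "no stimulation")
  expect_error(detectTriggers(rnorm(100), fs), "shorter")
})

test_that("detected triggers match the simulator ground truth", {
  ses <- cachedSession("small", smallCleanParams())
  trig <- detectTriggers(recordingEMG(ses$recording),
                         sampleRate(ses$recording))
  truthTrig <- triggerIndices(ses$recording)
  expect_length(trig, length(truthTrig))
  expect_true(all(abs(trig - truthTrig) <= 1))
})

test_that("zero-phase high-pass has no lag, kills DC, passes the band", {
  fs <- 2400
  t <- seq(0, 5, by = 1 / fs)
  x <- sin(2 * pi * 300 * t)
  y <- highpassZeroPhase(x, fs)
  cc <- ccf(x, y, lag.max = 10, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
  expect_gt(sd(y) / sd(x), 0.95)                       # passband ~unity

  x3 <- sin(2 * pi * 3 * t)
  expect_lt(sd(highpassZeroPhase(x3, fs)) / sd(x3), 0.01)

  xdc <- rnorm(length(t)) + 100
  expect_lt(abs(mean(highpassZeroPhase(xdc, fs))), 0.05)

  expect_error(highpassZeroPhase(x, fs, cutoffHz = 1300), "Nyquist")
})

test_that("filtering commutes with averaging (linearity)", {
  fs <- 2400
  epochs <- matrix(rnorm(6 * 480), nrow = 6)
  avgThenFilt <- highpassZeroPhase(matrix(colMeans(epochs), 1), fs)[1, ]
  filtThenAvg <- colMeans(highpassZeroPhase(epochs, fs))
  expect_equal(filtThenAvg, avgThenFilt, tolerance = 1e-10)
})

test_that("epochAverage computes the arithmetic mean on the 10-50 ms window", {
  fs <- 2400
  nCh <- 2
  sig <- matrix(0, nCh, 5 * fs)
  trig <- as.integer(c(1 * fs, 3 * fs))
  k <- ceiling(0.010 * fs):(ceiling(0.050 * fs) - 1)
  sig[1, trig[1] + k] <- 1:96
  sig[1, trig[2] + k] <- 96:1
  rec <- new("TrialRecording", data = sig, emg = numeric(5 * fs),
             sampleRate = fs, triggers = trig, channelIDs = c("a", "b"))
  tr <- epochAverage(rec)
  expect_equal(ncol(tr), 96)
  expect_equal(unname(traceValues(tr)[1, ]), rep(48.5, 96))
  expect_equal(range(timeAxis(tr)), c(10, 50 - 1000 / fs))
  expect_equal(nTrialsAveraged(tr), 2L)

  # an epoch running past the recording is dropped and counted
  rec2 <- new("TrialRecording", data = sig, emg = numeric(5 * fs),
              sampleRate = fs, triggers = c(trig, as.integer(5 * fs - 10)),
              channelIDs = c("a", "b"))
  tr2 <- epochAverage(rec2)
  expect_equal(nTrialsAveraged(tr2), 2L)
  expect_equal(S4Vectors::metadata(tr2)$n_dropped, 1L)
})

test_that("Savitzky-Golay reproduces cubics, keeps constants, shrinks noise", {
  tm <- seq(10, 50 - 1 / 2.4, by = 1 / 2.4)
  cubic <- (tm - 30)^3 / 100
  tr <- SSEPTrace(rbind(cubic, rep(2, length(tm))), tm, sampleRate = 2400)
  sm <- smoothSavGol(tr)
  expect_equal(unname(traceValues(sm)[1, ]), cubic, tolerance = 1e-9)
  expect_equal(unname(traceValues(sm)[2, ]), rep(2, length(tm)),
               tolerance = 1e-12)

  noise <- matrix(rnorm(4 * length(tm)), 4)
  trn <- SSEPTrace(noise, tm, sampleRate = 2400)
  smn <- smoothSavGol(trn)
  expect_lt(var(as.vector(traceValues(smn))), var(as.vector(noise)))

  expect_error(smoothSavGol(tr, windowLengthSamples = 12), "odd")
  expect_error(smoothSavGol(tr, polyorder = 3, windowLengthSamples = 3),
               "exceed")
})

test_that("corrupted-channel detection flags the large-variance channel", {
  tm <- seq(10, 50 - 1 / 2.4, by = 1 / 2.4)
  set.seed(7)
  v <- matrix(rnorm(32 * length(tm)), 32)
  v[13, ] <- rnorm(length(tm), sd = 20)
  tr <- SSEPTrace(v, tm)
  expect_identical(detectCorruptedChannels(tr), 13L)

  # all channels identical: nothing to flag
  same <- SSEPTrace(matrix(rep(sin(tm), 8), 8, byrow = TRUE), tm)
  expect_length(detectCorruptedChannels(same), 0)

  # clean simulator session: empty set
  ses <- cachedSession("small", smallCleanParams())
  tr2 <- cachedTrace("small", ses)
  expect_length(excludedChannels(tr2), 0)
  expect_error(detectCorruptedChannels(SSEPTrace(v[1:3, ], tm)), "4 channels")
})

test_that("corrupted channel injected by the simulator is found", {
  p <- smallCleanParams(seed = 21, corruptedChannelFraction = 1 / 32)
  ses <- cachedSession("corrupt1", p)
  tr <- cachedTrace("corrupt1", ses)
  expect_identical(excludedChannels(tr), corruptedChannels(ses$truth))
})

test_that("derivativeTrace matches analytic derivatives", {
  tm <- seq(10, 50 - 1 / 2.4, by = 1 / 2.4)
  tr <- SSEPTrace(rbind(rep(5, length(tm)), 3 * tm), tm)
  d <- derivativeTrace(tr)
  expect_equal(traceFlavor(d), "derivative")
  expect_equal(unname(traceValues(d)[1, ]), rep(0, length(tm)))
  expect_equal(unname(traceValues(d)[2, ]), rep(3, length(tm)),
               tolerance = 1e-9)

  # 100 Hz sinusoid: central-difference truncation bound on interior points
  f <- 0.1                                  # cycles per ms
  y <- sin(2 * pi * f * tm)
  dtr <- derivativeTrace(SSEPTrace(matrix(y, 1), tm))
  analytic <- 2 * pi * f * cos(2 * pi * f * tm)
  h <- tm[2] - tm[1]
  interior <- 2:(length(tm) - 1)
  err <- abs(traceValues(dtr)[1, interior] - analytic[interior])
  expect_lt(max(err), (2 * pi * f * h)^2)
})

test_that("z-scoring normalizes, is affine invariant, flips with sign", {
  tm <- seq(10, 50 - 1 / 2.4, by = 1 / 2.4)
  y <- sin(tm / 3) + 0.1 * tm
  tr <- SSEPTrace(rbind(y, 2.5 * y + 7, -0.5 * y + 1), tm)
  z <- zscoreTrace(tr)
  zv <- traceValues(z)
  for (ch in 1:3) {
    expect_lt(abs(mean(zv[ch, ])), 1e-10)
    expect_equal(var(zv[ch, ]), 1, tolerance = 1e-10)
  }
  expect_equal(zv[2, ], zv[1, ], tolerance = 1e-10)     # a > 0
  expect_equal(zv[3, ], -zv[1, ], tolerance = 1e-10)    # a < 0

  # zero-variance channel is flagged rather than divided
  trz <- SSEPTrace(rbind(y, rep(4, length(tm))), tm)
  expect_warning(z2 <- zscoreTrace(trz), "zero-variance")
  expect_identical(excludedChannels(z2), 2L)
  expect_true(all(traceValues(z2)[2, ] == 0))
})

test_that("the preprocessing chain is channel-order equivariant", {
  ses <- cachedSession("small", smallCleanParams())
  rec <- ses$recording
  perm <- rev(seq_len(nrow(recordingData(rec))))
  recP <- new("TrialRecording", data = recordingData(rec)[perm, ],
              emg = recordingEMG(rec), sampleRate = sampleRate(rec),
              triggers = triggerIndices(rec),
              channelIDs = rec@channelIDs[perm])
  a <- preprocessRecording(rec)
  b <- preprocessRecording(recP)
  expect_equal(unname(traceValues(b)), unname(traceValues(a)[perm, ]),
               tolerance = 1e-12)
})

test_that("the noiseless chain recovers template latencies within a sample", {
  p <- simParams(gridRows = 4, gridCols = 4, nTrials = 5, noiseSDuV = 0,
                 latencyJitterMS = 0, seed = 2)
  ses <- cachedSession("noiseless5", p)
  tr <- cachedTrace("noiseless5", ses)
  pk <- detectPeaks(tr, regionLabels(ses$truth))
  post <- pk$region == "posterior"
  expect_true(all(abs(pk$n1_latency_ms[post] - 20) <= 1000 / 2400 + 1e-9))
})
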