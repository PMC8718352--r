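test_that("ssepTemplate reproduces its closed form", {
  p <- simParams()
  t <- seq(0, 60, by = 1 / 2.4)

  # zero amplitudes give the zero waveform
  p0 <- simParams(componentAmplitudesUV = c(N20 = 0, P20 = 0, P25 = 0,
                                            P30 = 0),
                  anteriorLateAmpUV = 0)
  expect_equal(ssepTemplate("posterior", p0, t), rep(0, length(t)))
  expect_equal(ssepTemplate("anterior", p0, t), rep(0, length(t)))

  # isolated N20 bump: minimum in 17-25 ms is -A_N20 at the N20 latency
  pIso <- simParams(componentAmplitudesUV = c(N20 = 10, P20 = 0, P25 = 0,
                                              P30 = 0))
  w <- ssepTemplate("posterior", pIso, t)
  sel <- t >= 17 & t <= 25
  expect_equal(min(w[sel]), -10, tolerance = 1e-12)
  expect_equal(t[sel][which.min(w[sel])], 20, tolerance = 1 / 2.4)

  # phase reversal: opposite signs at the (matched) N20/P20 latency
  post <- ssepTemplate("posterior", p, t)
  ant <- ssepTemplate("anterior", p, t)
  i20 <- which.min(abs(t - 20))
  expect_lt(post[i20], 0)
  expect_gt(ant[i20], 0)

  expect_error(ssepTemplate("lateral", p, t), "unknown region")
})

test_that("spatialGain follows exp(-d/decay)", {
  src <- c(10, 10)
  expect_equal(spatialGain(c(10, 10), src, 15), 1)
  expect_equal(spatialGain(c(10 + 15, 10), src, 15), exp(-1),
               tolerance = 1e-12)
  # monotone non-increasing in distance
  d <- seq(0, 40, by = 2.5)
  g <- spatialGain(cbind(10 + d, 10), src, 15)
  expect_true(all(diff(g) <= 0))
  expect_error(spatialGain(c(0, 0), src, -1))
})

test_that("noiseless single-trial session round-trips the template x gain", {
  ses <- cachedSession("noiseless", noiselessParams())
  trace <- epochAverage(ses$recording)
  tm <- timeAxis(trace)
  pos <- positionsMM(ses$geometry)
  src <- ses$params@sourcePosition
  if (anyNA(src)) {
    csx <- mean(csLine(ses$geometry)[, 1])
    src <- c(min(csx + ses$params@spacingMM, max(pos[, 1])),
             0.6 * max(pos[, 2]))
  }
  gains <- spatialGain(pos, src, ses$params@spatialDecayMM)
  labels <- regionLabels(ses$truth)
  for (ch in c(1, 7, 16)) {
    expected <- gains[ch] * ssepTemplate(labels[ch], ses$params, tm)
    expect_equal(unname(traceValues(trace)[ch, ]), expected,
                 tolerance = 1e-12)
  }
})

test_that("simulateSession is reproducible given the seed", {
  p <- simParams(gridRows = 4, gridCols = 4, nTrials = 3, seed = 42)
  a <- simulateSession(p)
  b <- simulateSession(p)
  expect_identical(recordingData(a$recording), recordingData(b$recording))
  expect_identical(recordingEMG(a$recording), recordingEMG(b$recording))
  expect_identical(regionLabels(a$truth), regionLabels(b$truth))
})

test_that("a CS beyond the grid edge yields an all-posterior session", {
  p <- simPreset("no_crossing", gridRows = 4, gridCols = 4, nTrials = 2,
                 seed = 5)
  ses <- simulateSession(p)
  expect_true(all(regionLabels(ses$truth) == "posterior"))
  # and requesting a crossing there errors
  expect_error(simulateSession(simParams(gridRows = 4, gridCols = 4,
                                         csOffsetMM = -10, nTrials = 2)),
               "outside the grid")
})

test_that("averaged-trace variance scales as noise^2 / nTrials", {
  sampleVar <- function(nTrials, nRep = 50) {
    vals <- vapply(seq_len(nRep), function(s) {
      p <- simParams(gridRows = 2, gridCols = 2, nTrials = nTrials,
                     noiseSDuV = 10, latencyJitterMS = 0, seed = 1000 + s)
      ses <- simulateSession(p)
      traceValues(epochAverage(ses$recording))[1, 48]
    }, numeric(1))
    var(vals)
  }
  v4 <- sampleVar(4)
  v16 <- sampleVar(16)
  # expected 100/4 = 25 and 100/16 = 6.25; chi-square sampling slack
  expect_gt(v4 / 25, 0.5); expect_lt(v4 / 25, 1.9)
  expect_gt(v16 / 6.25, 0.5); expect_lt(v16 / 6.25, 1.9)
})

test_that("ground-truth labels are a geometric property, not an ordering one", {
  geom <- gridGeometry(5, 6, spacingMM = 5)
  labels <- regionsFromGeometry(geom)
  perm <- sample(length(labels))
  permGeom <- geom
  permGeom@positions <- positionsMM(geom)[perm, ]
  expect_identical(regionsFromGeometry(permGeom), labels[perm])
})

test_that("parameter validation rejects out-of-window latencies", {
  expect_error(simParams(componentLatenciesMS = c(N20 = 12)), "17")
  expect_error(simParams(componentLatenciesMS = c(P30 = 45)), "27")
  expect_error(simParams(nTrials = 0), "nTrials")
  expect_error(simParams(spatialDecayMM = 0), "spatialDecayMM")
  expect_error(simParams(bogus = 1), "unknown")
})

test_that("background noise is band-limited with the requested RMS", {
  set.seed(1)
  n <- ssepcs:::.backgroundNoise(1, 48000, 15, 70, 2400)[1, ]
  expect_equal(sd(n), 15, tolerance = 0.1)
  rho <- 1 - 2 * pi * 70 / 2400
  expect_equal(cor(n[-1], n[-length(n)]), rho, tolerance = 0.02)
  # most power sits below a few hundred Hz, unlike white noise
  hi <- highpassZeroPhase(n, 2400, cutoffHz = 400)
  expect_lt(var(hi) / var(n), 0.15)
  # white-noise degenerate case
  w <- ssepcs:::.backgroundNoise(1, 48000, 15, Inf, 2400)[1, ]
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.02)
})

test_that("corrupted channels carry the requested high variance", {
  p <- simParams(gridRows = 4, gridCols = 4, nTrials = 2, noiseSDuV = 5,
                 corruptedChannelFraction = 0.2, seed = 9)
  ses <- simulateSession(p)
  bad <- corruptedChannels(ses$truth)
  expect_length(bad, round(0.2 * 16))
  sds <- apply(recordingData(ses$recording), 1, sd)
  expect_true(all(sds[bad] > 5 * max(sds[-bad])))
})
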