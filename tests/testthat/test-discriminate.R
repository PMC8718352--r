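# independent brute-force evaluation of the Fisher criterion, kept loop-level
# so it cannot share a code path with fisherProfile()
bruteFisher <- function(values, labels) {
  idxA <- which(labels == "anterior")
  idxP <- which(labels == "posterior")
  out <- numeric(ncol(values))
  for (t in seq_len(ncol(values))) {
    a <- values[idxA, t]; p <- values[idxP, t]
    mA <- sum(a) / length(a); mP <- sum(p) / length(p)
    vA <- sum((a - mA)^2) / (length(a) - 1)
    vP <- sum((p - mP)^2) / (length(p) - 1)
    out[t] <- (mA - mP)^2 / (vA + vP)
  }
  out
}

test_that("fisherProfile matches the hand-evaluated definition", {
  tr <- SSEPTrace(rbind(c(1, 5), c(2, 5), c(3, 5), c(4, 5)), c(20, 30))
  labs <- c("anterior", "anterior", "posterior", "posterior")
  fp <- fisherProfile(tr, labs)
  # (1.5 - 3.5)^2 / (0.5 + 0.5) = 4 at the first time point
  expect_equal(fisherValues(fp)[1], 4)
  expect_equal(fp@muA[1], 1.5); expect_equal(fp@muP[1], 3.5)
  expect_equal(fp@varA[1], 0.5); expect_equal(fp@varP[1], 0.5)

  # equal class means with zero variances: F = 0, not NaN
  expect_equal(fisherValues(fp)[2], 0)

  # label swap leaves F unchanged
  swapped <- c(posterior = "anterior", anterior = "posterior")[labs]
  expect_equal(fisherValues(fisherProfile(tr, unname(swapped))),
               fisherValues(fp))

  # zero variance with unequal means: Inf, flagged
  tr2 <- SSEPTrace(rbind(c(1), c(1), c(2), c(2)), c(20))
  expect_warning(fp2 <- fisherProfile(tr2, labs), "Inf")
  expect_identical(fisherValues(fp2), Inf)

  expect_error(fisherProfile(SSEPTrace(rbind(1:2, 3:4, 5:6), c(20, 30)),
                             c("anterior", "posterior", "posterior")),
               "at least 2")
})

test_that("fisherProfile agrees with brute force on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    nA <- sample(2:6, 1); nP <- sample(2:6, 1); nt <- sample(3:10, 1)
    v <- matrix(rnorm((nA + nP) * nt), nA + nP)
    labs <- sample(c(rep("anterior", nA), rep("posterior", nP)))
    tm <- seq(15, 45, length.out = nt)
    got <- fisherValues(fisherProfile(SSEPTrace(v, tm), labs))
    want <- bruteFisher(v, labs)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("F(t) is invariant to common shifts and scalings", {
  set.seed(5)
  v <- matrix(rnorm(8 * 12), 8)
  labs <- rep(c("anterior", "posterior"), each = 4)
  tm <- seq(12, 48, length.out = 12)
  f0 <- fisherValues(fisherProfile(SSEPTrace(v, tm), labs))
  f1 <- fisherValues(fisherProfile(SSEPTrace(v + 7.3, tm), labs))
  f2 <- fisherValues(fisherProfile(SSEPTrace(v * 4.2, tm), labs))
  expect_equal(f1, f0, tolerance = 1e-10)
  expect_equal(f2, f0, tolerance = 1e-10)
})

test_that("detectPeaks reads template peaks and flags degenerate searches", {
  tm <- seq(10, 50 - 1 / 2.4, by = 1 / 2.4)
  p <- simParams(componentAmplitudesUV = c(N20 = 10, P20 = 6, P25 = 0,
                                           P30 = 8))
  post <- ssepTemplate("posterior", p, tm)
  ant <- ssepTemplate("anterior", p, tm)
  pk <- detectPeaks(SSEPTrace(rbind(post, ant), tm),
                    c("posterior", "anterior"))
  expect_equal(pk$n1_latency_ms[1], 20, tolerance = 1000 / 2400)
  expect_equal(pk$n1_amp_uV[1], 10, tolerance = 0.05)
  expect_equal(pk$p2_latency_ms[1], 31, tolerance = 1000 / 2400)
  expect_identical(pk$n1_flag[1], "ok")

  # purely positive-going waveform: no negative extremum in 17-25 ms
  pureUp <- ssepTemplate("anterior",
                         simParams(componentAmplitudesUV = c(P20 = 6),
                                   anteriorLateAmpUV = 0), tm)
  pk2 <- detectPeaks(SSEPTrace(matrix(pureUp, 1), tm))
  expect_identical(pk2$n1_flag[1], "boundary")

  # intermediate peaks in 22-30 ms are located but marked excluded
  p25 <- simParams(componentAmplitudesUV = c(N20 = 10, P20 = 6, P25 = 6,
                                             P30 = 8))
  pk3 <- detectPeaks(SSEPTrace(matrix(ssepTemplate("posterior", p25, tm), 1),
                               tm))
  expect_gte(pk3$n_intermediate_22_30[1], 1L)
})

test_that("peak latency is recovered within jitter across noisy seeds", {
  lat <- vapply(1:10, function(seed) {
    ses <- cachedSession(paste0("pk", seed), smallCleanParams(seed = 30 + seed))
    tr <- cachedTrace(paste0("pk", seed), ses)
    pk <- detectPeaks(tr, regionLabels(ses$truth))
    median(pk$n1_latency_ms[pk$region == "posterior"])
  }, numeric(1))
  expect_lt(abs(mean(lat) - 20), 0.5)
})

test_that("AUC follows the Mann-Whitney midrank convention", {
  expect_equal(aucFromScores(c(1, 2), c(5, 6))$auc, 1)      # separated
  expect_equal(aucFromScores(c(1, 2), c(1, 2))$auc, 0.5)    # identical
  r <- aucFromScores(c(1, 3), c(2, 4))
  expect_equal(r$auc, 0.75)                                  # 3/4 favorable
  expect_equal(r$auc_raw, 0.25)
  expect_identical(r$polarity, "B")
  # ties get midranks: {1,1} vs {1,2} -> P(a>b) + .5 P(=) = 0 + .5*.5 = 0.25
  expect_equal(aucFromScores(c(1, 1), c(1, 2))$auc_raw, 0.25)
  expect_error(aucFromScores(numeric(), 1:3), "non-empty")
})

test_that("AUC at a time point is rank invariant", {
  ses <- cachedSession("small", smallCleanParams())
  tr <- cachedTrace("small", ses)
  a1 <- rocAucAtTime(tr, ses$truth, 20)
  a2 <- rocAucAtTime(zscoreTrace(tr), ses$truth, 20)
  tr3 <- SSEPTrace(traceValues(tr) * 3.7, timeAxis(tr))
  a3 <- rocAucAtTime(tr3, regionLabels(ses$truth), 20)
  expect_equal(a2$auc, a1$auc)   # z-scoring changes values, not order?
  expect_equal(a3$auc, a1$auc)   # global scaling never changes order
})

test_that("pairedTTest handles regular and degenerate inputs", {
  a <- c(3, 1, 4, 1, 5)
  r0 <- pairedTTest(a, a)
  expect_equal(r0$statistic, 0); expect_equal(r0$p.value, 1)

  expect_warning(rInf <- pairedTTest(c(2, 3, 4, 5), c(1, 2, 3, 4)),
                 "zero variance")
  expect_identical(rInf$statistic, Inf)

  # differences {1, 2, 3}: t = 2 / (1 / sqrt(3)) = 3.4641
  r <- pairedTTest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-10)
  ref <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(r$p.value, ref$p.value)

  expect_error(pairedTTest(1:3, 1:4), "equal length")
})
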