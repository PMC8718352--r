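test_that("affinityMatrix evaluates the Gaussian similarity exactly", {
  # two waveforms at squared distance 8 with sigma = 2 -> exp(-1)
  x <- rbind(c(0, 0, 0, 0), c(2, 2, 0, 0))
  W <- affinityMatrix(x, sigma = 2)
  expect_equal(W[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(W[2, 1], W[1, 2])
  expect_equal(unname(diag(W)), c(1, 1))

  # identical waveforms -> affinity 1
  W2 <- affinityMatrix(rbind(1:4, 1:4), sigma = 2)
  expect_equal(W2[1, 2], 1)

  # excluded channels must be dropped upstream
  tm <- seq(10, 49, length.out = 4)
  tr <- markExcluded(SSEPTrace(matrix(rnorm(12), 3), tm), 2L)
  expect_error(affinityMatrix(tr), "excluded")
})

test_that("rwLaplacian reproduces hand-computed spectra", {
  # all-ones 3x3: L = I - J/3, eigenvalues {0, 1, 1}
  W <- matrix(1, 3, 3)
  lap <- rwLaplacian(W)
  expect_equal(lap$values, c(0, 1, 1), tolerance = 1e-10)
  expect_equal(lap$degrees, rep(3, 3))
  expect_equal(lap$L, diag(3) - W / 3, tolerance = 1e-12)

  # two disconnected blocks: two (near-)zero eigenvalues
  Wb <- matrix(0, 5, 5)
  Wb[1:2, 1:2] <- 1; Wb[3:5, 3:5] <- 1
  lapB <- rwLaplacian(Wb)
  expect_lt(abs(lapB$values[1]), 1e-10)
  expect_lt(abs(lapB$values[2]), 1e-10)
  expect_gt(lapB$values[3], 0.5)

  expect_error(rwLaplacian(matrix(0, 2, 2)), "row sum")
})

test_that("the smallest Laplacian eigenvalue is zero on random affinities", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    A <- matrix(runif(n * n, 0.01, 1), n)
    W <- (A + t(A)) / 2
    diag(W) <- 1
    lap <- rwLaplacian(W)
    expect_lt(abs(lap$values[1]), 1e-8)
    expect_true(all(lap$values >= 0))
  }
})

test_that("chooseKEigengap finds the elbow of the spectrum", {
  expect_identical(chooseKEigengap(c(0, 0.01, 0.9, 0.95)), 2L)
  expect_identical(chooseKEigengap(c(0, 0.8, 0.85, 0.9)), 1L)
  expect_error(chooseKEigengap(0.5), "at least 2")
})

test_that("well-separated identical waveforms split perfectly for any seed", {
  tm <- seq(10, 49, length.out = 20)
  a <- sin(tm / 3); b <- -sin(tm / 3) + cos(tm / 2)
  v <- rbind(a, a, a, a, b, b, b, b)
  tr <- SSEPTrace(v, tm)
  for (seed in c(1, 99, 12345)) {
    res <- spectralCluster(tr, seed = seed)
    expect_identical(chosenK(res), 2L)
    labs <- clusterLabels(res)
    expect_length(unique(labs[1:4]), 1)
    expect_length(unique(labs[5:8]), 1)
    expect_false(labs[1] == labs[5])
  }
})

test_that("clustering is deterministic and permutation equivariant", {
  ses <- cachedSession("small", smallCleanParams())
  tr <- cachedTrace("small", ses)
  der <- derivativeTrace(tr)
  r1 <- spectralCluster(der, seed = 7)
  r2 <- spectralCluster(der, seed = 7)
  expect_identical(clusterLabels(r1), clusterLabels(r2))

  set.seed(42)
  perm <- sample(nrow(der))
  derP <- SSEPTrace(traceValues(der)[perm, ], timeAxis(der),
                    flavor = traceFlavor(der))
  rP <- spectralCluster(derP, seed = 7)
  # same partition up to the permutation (cluster ids may swap)
  same <- outer(clusterLabels(r1)[perm], clusterLabels(r1)[perm], "==")
  sameP <- outer(clusterLabels(rP), clusterLabels(rP), "==")
  expect_equal(same, sameP, ignore_attr = TRUE)
  # and the spectrum is invariant
  expect_equal(rP@eigenvalues, r1@eigenvalues, tolerance = 1e-9)
})

test_that("1-D k-means matches the exhaustive contiguous-partition optimum", {
  # the optimal 1-D k-means partition is contiguous in sorted order, so
  # enumerating cut points is an exact oracle
  bruteWSS <- function(x, k) {
    xs <- sort(x)
    n <- length(xs)
    cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
    best <- Inf
    for (cp in cuts) {
      bounds <- c(0, cp, n)
      wss <- 0
      for (j in seq_len(k)) {
        seg <- xs[(bounds[j] + 1):bounds[j + 1]]
        wss <- wss + sum((seg - mean(seg))^2)
      }
      best <- min(best, wss)
    }
    best
  }
  wssOf <- function(x, labels) {
    sum(vapply(split(x, labels),
               function(seg) sum((seg - mean(seg))^2), numeric(1)))
  }
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    x <- rnorm(n)
    for (k in 2:3) {
      km <- ssepcs:::.kmeans1d(x, k, seed = rep)
      expect_equal(wssOf(x, km$labels), bruteWSS(x, k), tolerance = 1e-10)
    }
  }
})

test_that("clusteringAccuracy and the permutation complement identity hold", {
  truth <- rep(c("anterior", "posterior"), c(12, 20))
  expect_equal(clusteringAccuracy(truth, truth), 100)
  assigned <- truth; assigned[1:3] <- "posterior"
  expect_equal(clusteringAccuracy(assigned, truth), 100 * 29 / 32)
  flipped <- ifelse(assigned == "anterior", "posterior", "anterior")
  expect_equal(clusteringAccuracy(flipped, truth),
               100 - clusteringAccuracy(assigned, truth))
  expect_error(clusteringAccuracy(character(), character()), "non-empty")
})

test_that("assignRegions picks the accuracy-maximizing permutation", {
  tm <- seq(10, 49, length.out = 20)
  a <- sin(tm / 3); b <- -sin(tm / 3) + cos(tm / 2)
  tr <- SSEPTrace(rbind(a, a, a, b, b, b), tm)
  truth <- rep(c("posterior", "anterior"), each = 3)
  res <- spectralCluster(tr, seed = 1)
  res <- assignRegions(res, tr, truth)
  expect_gte(accuracyPct(res), 50)
  expect_equal(accuracyPct(res), 100)
  expect_equal(res@chlCL, 6)
  expect_equal(sum(res@confusion), 6)

  # all-anterior truth vs a forced 2-way split: accuracy = larger fraction
  res2 <- assignRegions(res, tr, rep("anterior", 6))
  expect_equal(accuracyPct(res2), 50)
})

test_that("the unsupervised polarity rule matches ground truth on clean data", {
  # channels carrying the two regional templates (clean N20 reversal)
  p <- simParams()
  tm <- seq(10, 50 - 1 / 2.4, by = 1 / 2.4)
  post <- ssepTemplate("posterior", p, tm)
  ant <- ssepTemplate("anterior", p, tm)
  set.seed(9)
  v <- rbind(t(replicate(4, post * runif(1, 0.5, 1))),
             t(replicate(4, ant * runif(1, 0.5, 1)))) +
    matrix(rnorm(8 * length(tm), 0, 0.05), 8)
  tr <- SSEPTrace(v, tm)
  truth <- rep(c("posterior", "anterior"), each = 4)
  res <- spectralCluster(tr, seed = 3)
  expect_identical(chosenK(res), 2L)
  unsup <- assignRegions(res, tr, groundTruth = NULL)
  sup <- assignRegions(res, tr, truth)
  expect_identical(unsup@regionMap, sup@regionMap)
  expect_equal(accuracyPct(sup), 100)
})

test_that("resampleGrids enumerates strips along the anterior-posterior axis", {
  # 8 x 4 grid with A-P along the row index: strips are the 4 grid columns
  # (length 8), plus 3 adjacent column pairs, plus the large grid
  ses <- cachedSession("small", smallCleanParams())
  tr <- cachedTrace("small", ses)
  rs <- resampleGrids(derivativeTrace(tr), ses$geometry, ses$truth, seed = 1)
  types <- vapply(rs$results, `[[`, character(1), "grid_type")
  expect_equal(sum(types == "1xN"), 4)
  expect_equal(sum(types == "2xN"), 3)
  expect_equal(sum(types == "large"), 1)
  oneN <- rs$results[types == "1xN"]
  expect_true(all(vapply(oneN, function(r) length(r$channels), integer(1))
                  == 8L))
  expect_identical(rs$summary$grid_type, c("1xN", "2xN", "large"))

  # degenerate 2 x 2 grid: both strips are skipped and logged
  p22 <- simParams(gridRows = 2, gridCols = 2, nTrials = 2, noiseSDuV = 1,
                   seed = 6)
  ses22 <- simulateSession(p22)
  tr22 <- epochAverage(ses22$recording)
  expect_message(rs22 <- resampleGrids(tr22, ses22$geometry, ses22$truth,
                                       seed = 1),
                 "skipping")
  expect_length(rs22$skipped, 2)
})
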