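#' @include preprocess.R
NULL

## subset a trace to a channel index set (keeps flavor and metadata;
## exclusion flags follow the channels)
.subsetTrace <- function(trace, idx) {
  excl <- which(idx %in% excludedChannels(trace))
  SSEPTrace(traceValues(trace)[idx, , drop = FALSE], timeAxis(trace),
            flavor = traceFlavor(trace), excluded = excl,
            nTrials = nTrialsAveraged(trace),
            sampleRate = metadata(trace)$sample_rate_hz,
            channelIDs = rowData(trace)$channel_id[idx])
}

#' Gaussian affinity matrix between channel waveforms
#'
#' `W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` with the Euclidean distance
#' between whole (normalized) waveforms; the diagonal is exactly 1. The
#' entries form the connectivity network between ECoG channels used for
#' spectral clustering.
#'
#' @param x an [SSEPTrace-class] of a z-scored flavor with no excluded
#'   channels present (drop them first with [dropExcluded()]), or a plain
#'   channels x features matrix.
#' @param sigma Gaussian width (default 2, the value that gives the least
#'   distorted clusters of normalized traces).
#' @return symmetric affinity matrix with unit diagonal.
#' @export
affinityMatrix <- function(x, sigma = 2) {
  if (is(x, "SSEPTrace")) {
    if (length(excludedChannels(x)))
      stop("excluded channels present; drop them before building affinities")
    if (!traceFlavor(x) %in% c("zscored", "zscored_derivative"))
      stop("affinity expects a z-scored trace flavor")
    x <- traceValues(x)
  }
  if (nrow(x) < 2L) stop("at least 2 channels are required")
  d2 <- as.matrix(stats::dist(x))^2
  W <- exp(-d2 / (2 * sigma^2))
  diag(W) <- 1
  W
}

#' Random-walk normalized graph Laplacian and its spectrum
#'
#' Computes `L = I - D^-1 W` with degree matrix `D_ii = sum_j W_ij`. For
#' numerical stability the eigenpairs are obtained from the symmetric
#' equivalent `I - D^-1/2 W D^-1/2` (same eigenvalues; eigenvectors mapped
#' back by `D^-1/2`). Eigenvalues are returned ascending, with the
#' constant-eigenvector eigenvalue ~0 first; negatives above -1e-10 are
#' clipped to zero.
#'
#' @param W symmetric affinity matrix with positive row sums; symmetrized as
#'   `(W + t(W))/2` before decomposition.
#' @return list with `W`, `degrees`, `L` (the random-walk Laplacian),
#'   `values` (ascending) and `vectors` (columns aligned with `values`).
#' @export
rwLaplacian <- function(W) {
  W <- (W + t(W)) / 2
  d <- rowSums(W)
  if (any(d <= 0)) stop("zero row sum: the affinity graph is disconnected from itself")
  n <- nrow(W)
  dInvSqrt <- 1 / sqrt(d)
  Lsym <- diag(n) - (dInvSqrt * W) * rep(dInvSqrt, each = n)
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  values[values < 0 & values > -1e-10] <- 0
  vectors <- eig$vectors[, ord, drop = FALSE] * dInvSqrt
  L <- diag(n) - W / d
  list(W = W, degrees = d, L = L, values = values, vectors = vectors)
}

#' Choose the number of clusters by the eigengap heuristic
#'
#' k is the position of the largest successive gap among the first
#' `kMax + 1` ascending eigenvalues (the "elbow" of the spectrum). When the
#' winning gap exceeds the runner-up by less than `gapFloor` the tie is
#' broken toward the smaller k. `k = 1` signals a single cluster - the
#' signature of a grid that did not cross the central sulcus.
#'
#' @param eigenvalues ascending Laplacian eigenvalues.
#' @param kMax largest k considered.
#' @param gapFloor minimum margin between the two largest gaps before the
#'   smaller-k tie-break applies.
#' @return integer k in 1..kMax.
#' @export
chooseKEigengap <- function(eigenvalues, kMax = 4, gapFloor = 0.05) {
  n <- length(eigenvalues)
  if (n < 2L) stop("need at least 2 eigenvalues")
  kMax <- min(kMax, n - 1L)
  gaps <- diff(eigenvalues)[seq_len(kMax)]
  ord <- order(gaps, decreasing = TRUE)
  k <- ord[1]
  if (length(ord) > 1L && gaps[ord[1]] - gaps[ord[2]] < gapFloor)
    k <- min(ord[1], ord[2])
  as.integer(k)
}

## 1-D k-means with deterministic quantile seeding plus random restarts;
## labels are renumbered so cluster centers ascend
.kmeans1d <- function(x, k, seed, restarts = 50) {
  ux <- sort(unique(x))
  if (length(ux) <= k) {
    ## at most k distinct values: the partition into distinct values is the
    ## exact within-SS optimum
    return(list(labels = match(x, ux), k = length(ux)))
  }
  xm <- matrix(x, ncol = 1)
  init <- matrix(quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE),
                 ncol = 1)
  if (anyDuplicated(init)) init <- matrix(ux[round(seq(1, length(ux),
                                                       length.out = k))],
                                          ncol = 1)
  ## kmeans may warn about Quick-TRANSfer non-convergence on near-duplicate
  ## 1-D data; the candidate labelings are still valid and the best-of-
  ## restarts WSS selection below is what guarantees the result
  best <- try(suppressWarnings(kmeans(xm, centers = init, iter.max = 100)),
              silent = TRUE)
  if (inherits(best, "try-error")) best <- NULL
  .withSeed(seed, {
    for (r in seq_len(restarts)) {
      cand <- try(suppressWarnings(
        kmeans(xm, centers = matrix(sample(ux, k), ncol = 1),
               iter.max = 100)), silent = TRUE)
      if (!inherits(cand, "try-error") &&
          (is.null(best) || cand$tot.withinss < best$tot.withinss))
        best <- cand
    }
  })
  if (is.null(best)) {
    ## deterministic fallback: cut the sorted values at their k-1 largest gaps
    cuts <- order(diff(sort(x)), decreasing = TRUE)[seq_len(k - 1L)]
    thr <- sort(sort(x)[cuts] + diff(sort(x))[cuts] / 2)
    return(list(labels = as.integer(findInterval(x, thr)) + 1L, k = k))
  }
  relabel <- rank(best$centers[, 1])
  list(labels = as.integer(relabel[best$cluster]), k = k)
}

#' Spectral clustering of channels by SSEP waveform
#'
#' Builds the Gaussian affinity between z-scored whole waveforms, the
#' random-walk normalized Laplacian, chooses k by the eigengap heuristic,
#' and (for k >= 2) runs k-means on the entries of the second-smallest
#' eigenvector - a 1-D embedding in which channels on opposite sides of the
#' central sulcus separate. Excluded channels are dropped first; raw or
#' derivative traces are z-scored internally. Deterministic given `seed`.
#'
#' @param trace an [SSEPTrace-class] (>= 3 channels after exclusions).
#' @param sigma Gaussian affinity width.
#' @param kMax,gapFloor eigengap settings, see [chooseKEigengap()].
#' @param seed RNG seed for the k-means restarts.
#' @param restarts number of random k-means restarts after the
#'   deterministic quantile seeding.
#' @return a [ClusterResult-class]; `clusterLabels()` is named by the
#'   original channel indices of `trace`.
#' @export
spectralCluster <- function(trace, sigma = 2, kMax = 4, gapFloor = 0.05,
                            seed = 1L, restarts = 50) {
  stopifnot(is(trace, "SSEPTrace"))
  if (!traceFlavor(trace) %in% c("zscored", "zscored_derivative"))
    trace <- zscoreTrace(trace)
  clean <- dropExcluded(trace)
  kept <- attr(clean, "keptChannels")
  if (nrow(clean) < 3L) stop("need at least 3 channels after exclusions")
  W <- affinityMatrix(clean, sigma = sigma)
  lap <- rwLaplacian(W)
  k <- chooseKEigengap(lap$values, kMax = kMax, gapFloor = gapFloor)
  emb <- lap$vectors[, 2]
  if (emb[which.max(abs(emb))] < 0) emb <- -emb     # fix sign ambiguity
  if (k >= 2L && sd(emb) < 1e-12) {
    warning("degenerate (constant) second eigenvector: falling back to k = 1")
    k <- 1L
  }
  if (k == 1L) {
    labels <- rep(1L, nrow(clean))
  } else {
    km <- .kmeans1d(emb, k, seed = seed, restarts = restarts)
    labels <- km$labels
    k <- as.integer(km$k)
  }
  names(labels) <- kept
  new("ClusterResult", k = k, labels = labels,
      regionMap = "single", accuracyPct = NA_real_, chlCL = NA_real_,
      confusion = matrix(numeric(), 0, 0), eigenvalues = lap$values,
      eigengaps = diff(lap$values), embedding = emb, sigma = sigma,
      seed = as.integer(seed))
}

#' Clustering accuracy against ground truth
#'
#' `100 * CHL_CL / total`, where CHL_CL is the number of channels whose
#' assigned region matches the ground truth. Both inputs must cover the
#' same (non-excluded) channel set.
#'
#' @param assigned character region per channel.
#' @param truth character ground-truth region per channel.
#' @return accuracy in percent.
#' @export
clusteringAccuracy <- function(assigned, truth) {
  if (!length(assigned) || length(assigned) != length(truth))
    stop("assigned and truth must be non-empty and of equal length")
  100 * sum(assigned == truth) / length(truth)
}

#' Map clusters to anterior/posterior regions
#'
#' For a 2-cluster result: with ground truth, the cluster-to-region mapping
#' maximizing the accuracy over the two possible permutations is chosen;
#' without ground truth, the cluster whose mean trace has the more negative
#' extremum in the 17-25 ms window (the N20 polarity) is called posterior.
#' For k != 2 the region map is "single" and no accuracy is computed.
#'
#' @param result a [ClusterResult-class].
#' @param trace the [SSEPTrace-class] the result was computed from (used for
#'   the polarity rule and to align channels).
#' @param groundTruth optional [GroundTruth-class] or per-channel region
#'   labels for the full trace channel set.
#' @return the result with `regionMap`, and with ground truth also
#'   `accuracyPct`, `chlCL` and `confusion`, filled in.
#' @export
assignRegions <- function(result, trace, groundTruth = NULL) {
  if (result@k != 2L) {
    result@regionMap <- "single"
    return(result)
  }
  kept <- as.integer(names(clusterLabels(result)))
  labs <- clusterLabels(result)
  if (!is.null(groundTruth)) {
    truth <- if (is(groundTruth, "GroundTruth")) regionLabels(groundTruth)
             else groundTruth
    truth <- truth[kept]
    maps <- list(c("anterior", "posterior"), c("posterior", "anterior"))
    accs <- vapply(maps, function(m) clusteringAccuracy(m[labs], truth),
                   numeric(1))
    best <- maps[[which.max(accs)]]
    assigned <- best[labs]
    result@regionMap <- best
    result@accuracyPct <- max(accs)
    result@chlCL <- sum(assigned == truth)
    tab <- table(assigned = factor(assigned, c("anterior", "posterior")),
                 truth = factor(truth, c("anterior", "posterior")))
    result@confusion <- matrix(as.numeric(tab), 2, 2,
                               dimnames = dimnames(tab))
  } else {
    v <- traceValues(trace)[kept, , drop = FALSE]
    tm <- timeAxis(trace)
    sel <- which(tm >= 17 & tm <= 25)
    minByCluster <- vapply(1:2, function(cl)
      min(colMeans(v[labs == cl, , drop = FALSE])[sel]), numeric(1))
    post <- which.min(minByCluster)
    m <- c("anterior", "anterior")
    m[post] <- "posterior"
    result@regionMap <- m
  }
  result
}

#' Cluster resampled sub-grids (strips and double rows)
#'
#' Runs the electrode-size study: every 1 x N strip running
#' along the anterior-posterior axis, every adjacent 2 x N pair, and the
#' full grid are clustered separately. Subsets with fewer than 3 usable
#' channels are skipped (and listed). Subsets that come back with a single
#' cluster (or k > 2) are scored as the majority-class fraction, so a
#' one-cluster call on a sulcus-crossing strip is penalized.
#'
#' @param trace an [SSEPTrace-class] over the full grid.
#' @param geometry the [GridGeometry-class] of the grid.
#' @param groundTruth a [GroundTruth-class] (needed for accuracies).
#' @param sigma,kMax,gapFloor,seed,restarts passed to [spectralCluster()].
#' @return list with `results` (per-subset list: channels, grid_type, k,
#'   accuracy), `summary` (data.frame: grid_type, n_subsets, mean_acc,
#'   sd_acc) and `skipped` (list of skipped channel sets).
#' @export
resampleGrids <- function(trace, geometry, groundTruth, sigma = 2, kMax = 4,
                          gapFloor = 0.05, seed = 1L, restarts = 50) {
  if (geometry@nRows < 2L || geometry@nCols < 2L)
    stop("resampling needs a grid with at least 2 rows and 2 columns")
  gi <- .gridIndex(geometry)
  ## strips extend along the anterior-posterior axis
  if (geometry@apAxis == "column") {
    lanes <- lapply(seq_len(geometry@nRows), function(r) which(gi$row == r))
  } else {
    lanes <- lapply(seq_len(geometry@nCols), function(c) which(gi$col == c))
  }
  subsets <- c(
    lapply(lanes, function(ch) list(channels = ch, grid_type = "1xN")),
    lapply(seq_len(length(lanes) - 1L), function(i)
      list(channels = sort(c(lanes[[i]], lanes[[i + 1L]])),
           grid_type = "2xN")),
    list(list(channels = seq_len(nrow(trace)), grid_type = "large"))
  )
  truth <- regionLabels(groundTruth)
  results <- list()
  skipped <- list()
  for (s in subsets) {
    usable <- setdiff(s$channels, excludedChannels(trace))
    if (length(usable) < 3L) {
      message("skipping ", s$grid_type, " subset with < 3 usable channels: ",
              paste(s$channels, collapse = ","))
      skipped <- c(skipped, list(s))
      next
    }
    sub <- .subsetTrace(trace, s$channels)
    res <- spectralCluster(sub, sigma = sigma, kMax = kMax,
                           gapFloor = gapFloor, seed = seed,
                           restarts = restarts)
    if (res@k == 2L) {
      subTruth <- truth[s$channels]
      res <- assignRegions(res, sub, subTruth)
      acc <- accuracyPct(res)
    } else {
      ## no region mapping possible: score as majority-class fraction
      kept <- s$channels[as.integer(names(clusterLabels(res)))]
      tt <- table(truth[kept])
      acc <- 100 * max(tt) / sum(tt)
    }
    results <- c(results, list(list(channels = s$channels,
                                    grid_type = s$grid_type, k = res@k,
                                    accuracy = acc, result = res)))
  }
  df <- data.frame(
    grid_type = vapply(results, `[[`, character(1), "grid_type"),
    accuracy = vapply(results, `[[`, numeric(1), "accuracy")
  )
  summary <- do.call(rbind, lapply(split(df, df$grid_type), function(g)
    data.frame(grid_type = g$grid_type[1], n_subsets = nrow(g),
               mean_acc = mean(g$accuracy),
               sd_acc = if (nrow(g) > 1) sd(g$accuracy) else NA_real_)))
  summary <- summary[match(c("1xN", "2xN", "large"), summary$grid_type), ]
  rownames(summary) <- NULL
  list(results = results, summary = summary, skipped = skipped)
}

#' Sweep the affinity width sigma
#'
#' Reruns [spectralCluster()] for a range of sigma values, mirroring the
#' procedure used to settle on sigma = 2.
#'
#' @param trace an [SSEPTrace-class].
#' @param sigmas numeric vector of widths to try.
#' @param groundTruth optional truth for accuracies.
#' @param ... passed to [spectralCluster()].
#' @return data.frame with sigma, k and accuracy (NA without truth).
#' @export
sigmaSweep <- function(trace, sigmas = c(0.5, 1, 2, 4, 8),
                       groundTruth = NULL, ...) {
  rows <- lapply(sigmas, function(s) {
    res <- spectralCluster(trace, sigma = s, ...)
    acc <- NA_real_
    if (!is.null(groundTruth) && res@k == 2L)
      acc <- accuracyPct(assignRegions(res, trace, groundTruth))
    data.frame(sigma = s, k = res@k, accuracy = acc)
  })
  do.call(rbind, rows)
}
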