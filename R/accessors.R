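#' @include AllGenerics.R
NULL

## ---- SSEPTrace ----

#' Construct an SSEPTrace
#'
#' @param values channels x timepoints matrix.
#' @param timeMs time axis in ms post-stimulus (inside the 10-50 ms window).
#' @param flavor one of raw, derivative, zscored, zscored_derivative.
#' @param excluded logical or integer index of excluded (corrupted) channels.
#' @param nTrials number of trials averaged into the trace.
#' @param sampleRate sampling rate (Hz) of the source recording.
#' @param channelIDs optional channel identifiers.
#' @return an [SSEPTrace-class] object.
#' @export
SSEPTrace <- function(values, timeMs, flavor = "raw", excluded = integer(),
                      nTrials = NA_integer_, sampleRate = NA_real_,
                      channelIDs = NULL) {
  values <- as.matrix(values)
  if (is.null(channelIDs))
    channelIDs <- if (!is.null(rownames(values))) rownames(values)
                  else sprintf("ch%02d", seq_len(nrow(values)))
  excl <- rep(FALSE, nrow(values))
  excl[excluded] <- TRUE
  dimnames(values) <- list(channelIDs, NULL)
  se <- SummarizedExperiment(
    assays = list(values = values),
    rowData = DataFrame(channel_id = channelIDs, excluded = excl),
    colData = DataFrame(time_ms = as.numeric(timeMs))
  )
  metadata(se) <- list(flavor = flavor, n_trials = as.integer(nTrials),
                       sample_rate_hz = sampleRate)
  new("SSEPTrace", se)
}

#' @describeIn SSEPTrace channels x timepoints value matrix.
#' @param x an SSEPTrace.
#' @export
setMethod("traceValues", "SSEPTrace", function(x) assay(x, "values"))

#' @describeIn SSEPTrace time axis in ms.
#' @export
setMethod("timeAxis", "SSEPTrace", function(x) colData(x)$time_ms)

#' @describeIn SSEPTrace trace flavor string.
#' @export
setMethod("traceFlavor", "SSEPTrace", function(x) metadata(x)$flavor)

#' @describeIn SSEPTrace integer indices of excluded channels.
#' @export
setMethod("excludedChannels", "SSEPTrace",
          function(x) which(rowData(x)$excluded))

#' @describeIn SSEPTrace number of trials averaged.
#' @export
setMethod("nTrialsAveraged", "SSEPTrace",
          function(x) metadata(x)$n_trials)

setMethod("show", "SSEPTrace", function(object) {
  cat(sprintf("SSEPTrace (%s): %d channels x %d timepoints, %.1f-%.1f ms\n",
              traceFlavor(object), nrow(object), ncol(object),
              min(timeAxis(object)), max(timeAxis(object))))
  ne <- length(excludedChannels(object))
  cat(sprintf("  trials averaged: %s; excluded channels: %d\n",
              nTrialsAveraged(object), ne))
})

#' Replace trace values, keeping metadata
#'
#' @param x an SSEPTrace.
#' @param values replacement matrix of identical dimensions.
#' @param flavor optional new flavor.
#' @return an SSEPTrace.
#' @keywords internal
setTraceValues <- function(x, values, flavor = traceFlavor(x)) {
  stopifnot(identical(dim(values), dim(traceValues(x))))
  SSEPTrace(values, timeAxis(x), flavor = flavor,
            excluded = excludedChannels(x), nTrials = nTrialsAveraged(x),
            sampleRate = metadata(x)$sample_rate_hz,
            channelIDs = rowData(x)$channel_id)
}

#' Mark channels as excluded (corrupted)
#'
#' @param trace an SSEPTrace.
#' @param idx integer channel indices to exclude (added to any existing set).
#' @return the trace with its exclusion set extended.
#' @export
markExcluded <- function(trace, idx) {
  excl <- union(excludedChannels(trace), as.integer(idx))
  SSEPTrace(traceValues(trace), timeAxis(trace), flavor = traceFlavor(trace),
            excluded = excl, nTrials = nTrialsAveraged(trace),
            sampleRate = metadata(trace)$sample_rate_hz,
            channelIDs = rowData(trace)$channel_id)
}

#' Drop excluded channels from a trace
#'
#' @param trace an SSEPTrace.
#' @return the trace restricted to non-excluded channels. Row names keep the
#'   original channel ids; the mapping back to original indices is in
#'   `attr(, "keptChannels")`.
#' @export
dropExcluded <- function(trace) {
  keep <- setdiff(seq_len(nrow(trace)), excludedChannels(trace))
  out <- SSEPTrace(traceValues(trace)[keep, , drop = FALSE], timeAxis(trace),
                   flavor = traceFlavor(trace), excluded = integer(),
                   nTrials = nTrialsAveraged(trace),
                   sampleRate = metadata(trace)$sample_rate_hz,
                   channelIDs = rowData(trace)$channel_id[keep])
  attr(out, "keptChannels") <- keep
  out
}

## ---- GridGeometry ----

#' @describeIn gridGeometry electrode positions (channels x 2 matrix, mm).
#' @export
setMethod("positionsMM", "GridGeometry", function(x) x@positions)

#' @describeIn gridGeometry CS polyline (mm).
#' @export
setMethod("csLine", "GridGeometry", function(x) x@csLine)

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d grid, %.1f mm pitch, A-P along %ss\n",
              object@nRows, object@nCols, object@spacingMM, object@apAxis))
  if (nrow(object@csLine))
    cat(sprintf("  CS line through x = %.1f mm\n", mean(object@csLine[, 1])))
})

## ---- TrialRecording ----

setMethod("show", "TrialRecording", function(object) {
  cat(sprintf(
    "TrialRecording: %d channels x %d samples @ %.0f Hz (%.1f s), %d triggers\n",
    nrow(object@data), ncol(object@data), object@sampleRate,
    ncol(object@data) / object@sampleRate, length(object@triggers)))
})

#' Accessors for TrialRecording
#'
#' @param x a TrialRecording.
#' @name recording-accessors
NULL

#' @rdname recording-accessors
#' @export
recordingData <- function(x) x@data

#' @rdname recording-accessors
#' @export
recordingEMG <- function(x) x@emg

#' @rdname recording-accessors
#' @export
sampleRate <- function(x) x@sampleRate

#' @rdname recording-accessors
#' @export
triggerIndices <- function(x) x@triggers

## ---- GroundTruth ----

#' @describeIn simulateSession per-channel region labels of a ground truth.
#' @export
setMethod("regionLabels", "GroundTruth", function(x) x@regionLabels)

#' @export
setMethod("corruptedChannels", "GroundTruth", function(x) x@corruptedChannels)

#' @export
setMethod("csLine", "GroundTruth", function(x) x@csLine)

setMethod("show", "GroundTruth", function(object) {
  tab <- table(factor(object@regionLabels,
                      levels = c("anterior", "posterior", "excluded")))
  cat(sprintf("GroundTruth: %d anterior, %d posterior channels; %d corrupted\n",
              tab[["anterior"]], tab[["posterior"]],
              length(object@corruptedChannels)))
})

## ---- FisherProfile ----

#' @describeIn fisherProfile the F(t) vector.
#' @export
setMethod("fisherValues", "FisherProfile", function(x) x@F)

#' @describeIn fisherProfile time axis of the profile.
#' @export
setMethod("timeAxis", "FisherProfile", function(x) x@tMs)

#' @describeIn fisherProfile summary of discriminative peaks: the global
#'   argmax of F(t) plus the windowed maxima F_N20 (17-25 ms) and F_P30
#'   (27-40 ms), each with its time and value.
#' @export
setMethod("discriminativePeaks", "FisherProfile", function(x) {
  pk <- function(lo, hi) {
    sel <- which(x@tMs >= lo & x@tMs <= hi)
    i <- sel[which.max(x@F[sel])]
    c(t_ms = x@tMs[i], F = x@F[i])
  }
  iAll <- which.max(x@F)
  list(argmax = c(t_ms = x@tMs[iAll], F = x@F[iAll]),
       F_N20 = pk(17, 25), F_P30 = pk(27, 40))
})

setMethod("show", "FisherProfile", function(object) {
  pk <- discriminativePeaks(object)
  cat(sprintf("FisherProfile (%s flavor), %d timepoints\n",
              object@flavor, length(object@tMs)))
  cat(sprintf("  max F = %.3f at %.2f ms; F_N20 = %.3f @ %.2f ms; F_P30 = %.3f @ %.2f ms\n",
              pk$argmax["F"], pk$argmax["t_ms"], pk$F_N20["F"],
              pk$F_N20["t_ms"], pk$F_P30["F"], pk$F_P30["t_ms"]))
})

## ---- ClusterResult ----

#' @describeIn spectralCluster per-channel cluster labels.
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @describeIn spectralCluster the eigengap-chosen number of clusters.
#' @export
setMethod("chosenK", "ClusterResult", function(x) x@k)

#' @describeIn spectralCluster clustering accuracy in percent (NA without
#'   ground truth).
#' @export
setMethod("accuracyPct", "ClusterResult", function(x) x@accuracyPct)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d over %d channels (sigma = %.2f)\n",
              object@k, length(object@labels), object@sigma))
  if (length(object@regionMap) && !identical(object@regionMap, "single"))
    cat(sprintf("  region map: %s\n",
                paste(sprintf("%d->%s", seq_along(object@regionMap),
                              object@regionMap), collapse = ", ")))
  if (!is.na(object@accuracyPct))
    cat(sprintf("  accuracy vs ground truth: %.1f%% (%d correct)\n",
                object@accuracyPct, object@chlCL))
})

setMethod("show", "HeatMapFrame", function(object) {
  cat(sprintf("HeatMapFrame at %.1f ms: %d x %d raster, %s scale [%.2f, %.2f]\n",
              object@tMs, nrow(object@image), ncol(object@image),
              object@scaleMode, object@limits[1], object@limits[2]))
})
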