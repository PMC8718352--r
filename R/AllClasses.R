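#' @include ssepcs-package.R
NULL

## Grid coordinate convention used throughout:
##   x (mm) increases anterior -> posterior, y (mm) increases medial -> lateral.
##   Channels are stored row-major: channel = (row - 1) * nCols + col.
##   `apAxis` says which grid index maps onto x: "column" (default; the column
##   index moves anterior->posterior) or "row".

#' Electrode grid geometry
#'
#' Positions of the electrodes of a regular subdural grid in millimetres,
#' together with the (presumed or simulated) central sulcus line. The CS line
#' is stored as a polyline in the same (x = anterior-posterior,
#' y = medial-lateral) coordinates.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot spacingMM electrode pitch in mm (clinical grids use 5 or 10).
#' @slot apAxis which grid index runs anterior->posterior: "column" or "row".
#' @slot positions numeric matrix (channels x 2), columns x and y in mm.
#' @slot csLine numeric matrix (points x 2) polyline of the CS, or a 0-row
#'   matrix when no line is known.
#' @exportClass GridGeometry
setClass("GridGeometry",
  representation(
    nRows = "integer",
    nCols = "integer",
    spacingMM = "numeric",
    apAxis = "character",
    positions = "matrix",
    csLine = "matrix"
  )
)

setValidity("GridGeometry", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid must have at least one row and one column")
  if (!object@apAxis %in% c("row", "column"))
    msg <- c(msg, "apAxis must be 'row' or 'column'")
  if (nrow(object@positions) != object@nRows * object@nCols ||
      ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be (nRows*nCols) x 2")
  if (!(length(object@spacingMM) == 1L && object@spacingMM > 0))
    msg <- c(msg, "spacingMM must be a single positive number")
  if (ncol(object@csLine) != 2L && nrow(object@csLine) > 0L)
    msg <- c(msg, "csLine must have 2 columns")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel recording with an EMG trigger channel
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot emg numeric vector of surface EMG samples (microvolts); carries the
#'   stimulation artifact spikes used for trigger detection.
#' @slot sampleRate sampling rate in Hz.
#' @slot triggers integer sample indices of stimulation onsets (may be empty,
#'   in which case they are detected from the EMG).
#' @slot channelIDs character channel identifiers.
#' @exportClass TrialRecording
setClass("TrialRecording",
  representation(
    data = "matrix",
    emg = "numeric",
    sampleRate = "numeric",
    triggers = "integer",
    channelIDs = "character"
  )
)

setValidity("TrialRecording", function(object) {
  msg <- character()
  if (object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be positive")
  if (length(object@emg) != ncol(object@data))
    msg <- c(msg, "emg must have one sample per data column")
  if (length(object@channelIDs) != nrow(object@data))
    msg <- c(msg, "channelIDs must match the number of channels")
  if (length(object@triggers) > 1L && any(diff(object@triggers) <= 0L))
    msg <- c(msg, "triggers must be strictly increasing")
  if (length(object@triggers) &&
      (min(object@triggers) < 1L || max(object@triggers) > ncol(object@data)))
    msg <- c(msg, "triggers must lie inside the recording")
  if (length(msg)) msg else TRUE
})

#' Averaged SSEP traces on the 10-50 ms post-stimulus window
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] wrapper: rows are
#' channels, columns are time points. `colData$time_ms` holds the time axis,
#' `rowData$excluded` flags corrupted channels, and `metadata()` records the
#' flavor (`raw`, `derivative`, `zscored`, `zscored_derivative`), the number
#' of trials averaged and the sample rate. Raw traces are in microvolts,
#' derivative traces in microvolts per millisecond.
#'
#' @exportClass SSEPTrace
setClass("SSEPTrace", contains = "SummarizedExperiment")

.TRACE_FLAVORS <- c("raw", "derivative", "zscored", "zscored_derivative")

setValidity("SSEPTrace", function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$flavor) || !md$flavor %in% .TRACE_FLAVORS)
    msg <- c(msg, sprintf("flavor must be one of %s",
                          paste(.TRACE_FLAVORS, collapse = ", ")))
  tm <- colData(object)$time_ms
  if (is.null(tm)) {
    msg <- c(msg, "colData must carry time_ms")
  } else {
    if (any(diff(tm) <= 0)) msg <- c(msg, "time_ms must be increasing")
    if (tm[1] < 10 - 1e-9 || tm[length(tm)] > 50 + 1e-9)
      msg <- c(msg, "time axis must lie inside the 10-50 ms window")
  }
  if (is.null(rowData(object)$excluded))
    msg <- c(msg, "rowData must carry an 'excluded' logical column")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated session
#'
#' @slot regionLabels character per channel, "anterior" or "posterior"
#'   (side of the CS line); corrupted channels keep their geometric label and
#'   are listed in `corruptedChannels`.
#' @slot csLine the generating CS polyline (mm).
#' @slot corruptedChannels integer indices of channels replaced by
#'   high-variance noise.
#' @slot trueLatencies named numeric, generating component latencies (ms).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    regionLabels = "character",
    csLine = "matrix",
    corruptedChannels = "integer",
    trueLatencies = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@regionLabels %in% c("anterior", "posterior", "excluded")))
    msg <- c(msg, "regionLabels must be anterior/posterior/excluded")
  if (length(object@corruptedChannels) &&
      (min(object@corruptedChannels) < 1L ||
       max(object@corruptedChannels) > length(object@regionLabels)))
    msg <- c(msg, "corruptedChannels must index the channel set")
  if (length(msg)) msg else TRUE
})

#' Fisher discriminant profile over time
#'
#' Per-time-point separability between anterior and posterior channels,
#' F(t) = (muA - muP)^2 / (varA + varP) with n-1 sample variances.
#'
#' @slot F numeric separability per time point (>= 0, may be Inf when both
#'   class variances vanish with unequal means).
#' @slot muA,muP class means per time point.
#' @slot varA,varP class sample variances per time point.
#' @slot tMs time axis (ms).
#' @slot flavor trace flavor the profile was computed from.
#' @exportClass FisherProfile
setClass("FisherProfile",
  representation(
    F = "numeric",
    muA = "numeric",
    muP = "numeric",
    varA = "numeric",
    varP = "numeric",
    tMs = "numeric",
    flavor = "character"
  )
)

setValidity("FisherProfile", function(object) {
  n <- length(object@tMs)
  if (!all(lengths(list(object@F, object@muA, object@muP,
                        object@varA, object@varP)) == n))
    return("all profile vectors must share the time-axis length")
  if (any(object@F < -1e-12, na.rm = TRUE))
    return("F must be non-negative")
  TRUE
})

#' Spectral clustering result
#'
#' @slot k chosen number of clusters (eigengap heuristic; k = 1 signals a
#'   single cluster, i.e. no CS crossing detected).
#' @slot labels integer cluster id per (non-excluded) channel, named by
#'   channel index in the original trace.
#' @slot regionMap character mapping cluster id -> "anterior"/"posterior",
#'   or "single" when k != 2.
#' @slot accuracyPct 100 * correctly clustered channels / total channels
#'   (NA without ground truth).
#' @slot chlCL number of correctly clustered channels (NA without truth).
#' @slot confusion 2x2 confusion matrix (cluster-region vs truth), possibly
#'   0 x 0.
#' @slot eigenvalues ascending eigenvalues of the random-walk Laplacian.
#' @slot eigengaps successive differences of the sorted eigenvalues.
#' @slot embedding entries of the second-smallest eigenvector (the 1-D
#'   k-means embedding).
#' @slot sigma Gaussian affinity width used.
#' @slot seed RNG seed used for the k-means restarts.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    k = "integer",
    labels = "integer",
    regionMap = "character",
    accuracyPct = "numeric",
    chlCL = "numeric",
    confusion = "matrix",
    eigenvalues = "numeric",
    eigengaps = "numeric",
    embedding = "numeric",
    sigma = "numeric",
    seed = "integer"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (!is.na(object@accuracyPct) &&
      (object@accuracyPct < 0 || object@accuracyPct > 100))
    msg <- c(msg, "accuracyPct must lie in [0, 100]")
  if (length(object@labels) && max(object@labels) > object@k)
    msg <- c(msg, "labels must not exceed k")
  if (length(msg)) msg else TRUE
})

#' A rendered spatial heat-map frame
#'
#' Dense interpolated amplitude field over the grid bounding box at one time
#' point, exact at the electrode positions.
#'
#' @slot image numeric matrix (ny x nx) of interpolated values (microvolts,
#'   or the trace's units).
#' @slot xMM,yMM raster axes in mm.
#' @slot tMs frame time (ms).
#' @slot limits length-2 color limits.
#' @slot scaleMode "symmetric" (limits = +/- max|value|) or "asymmetric".
#' @slot electrodes data.frame with x, y, value, excluded per electrode.
#' @slot csLine CS polyline overlay (possibly 0-row).
#' @exportClass HeatMapFrame
setClass("HeatMapFrame",
  representation(
    image = "matrix",
    xMM = "numeric",
    yMM = "numeric",
    tMs = "numeric",
    limits = "numeric",
    scaleMode = "character",
    electrodes = "data.frame",
    csLine = "matrix"
  )
)

setValidity("HeatMapFrame", function(object) {
  msg <- character()
  if (!identical(dim(object@image), c(length(object@yMM), length(object@xMM))))
    msg <- c(msg, "image must be length(yMM) x length(xMM)")
  if (length(object@limits) != 2L)
    msg <- c(msg, "limits must have length 2")
  if (object@scaleMode == "symmetric" &&
      !isTRUE(all.equal(object@limits[2], -object@limits[1])))
    msg <- c(msg, "symmetric scale requires limits = +/- max|value|")
  if (length(msg)) msg else TRUE
})
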