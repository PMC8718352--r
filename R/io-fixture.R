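#' @include simulate.R
NULL

## ---------------------------------------------------------------------------
## Fixture bundle: a directory with the continuous signal as a raw float64
## array (column-major channels x samples), the EMG, and a JSON sidecar
## carrying geometry, ground truth, parameters and the seed. This is the
## package's own session format; EDF+ export is in io-edf.R.
## ---------------------------------------------------------------------------

.geometryToList <- function(geometry, truth = NULL) {
  g <- list(rows = geometry@nRows, cols = geometry@nCols,
            spacing_mm = geometry@spacingMM, ap_axis = geometry@apAxis,
            positions_mm = unname(apply(positionsMM(geometry), 1, c,
                                        simplify = FALSE)),
            cs_line = unname(apply(csLine(geometry), 1, c, simplify = FALSE)))
  if (!is.null(truth)) {
    g$region_labels <- regionLabels(truth)
    g$corrupted_channels <- corruptedChannels(truth)
    g$true_latencies_ms <- as.list(truth@trueLatencies)
  }
  g
}

.geometryFromList <- function(g) {
  pos <- do.call(rbind, g$positions_mm)
  cs <- do.call(rbind, g$cs_line)
  colnames(pos) <- c("x", "y"); colnames(cs) <- c("x", "y")
  new("GridGeometry", nRows = as.integer(g$rows), nCols = as.integer(g$cols),
      spacingMM = g$spacing_mm, apAxis = g$ap_axis, positions = pos,
      csLine = cs)
}

#' Write a simulated session as a fixture bundle
#'
#' @param session list from [simulateSession()].
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
writeSessionBundle <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  con <- file(file.path(dir, "signal.bin"), "wb")
  writeBin(as.vector(rec@data), con, size = 8, endian = "little")
  close(con)
  con <- file(file.path(dir, "emg.bin"), "wb")
  writeBin(rec@emg, con, size = 8, endian = "little")
  close(con)
  p <- session$params
  meta <- list(
    n_channels = nrow(rec@data), n_samples = ncol(rec@data),
    sample_rate_hz = rec@sampleRate, triggers = rec@triggers,
    channel_ids = rec@channelIDs,
    geometry = .geometryToList(session$geometry, session$truth),
    params = if (!is.null(p)) .paramsToList(p)
  )
  ## na = "string" keeps NA / Inf parameter values round-trippable
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "string"),
             file.path(dir, "meta.json"))
  invisible(dir)
}

## named vectors must become JSON objects (arrays drop names)
.paramsToList <- function(p) {
  nm <- slotNames(p)
  out <- lapply(nm, function(s) {
    v <- slot(p, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  stats::setNames(out, nm)
}

.paramsFromList <- function(pl) {
  namedNum <- function(x) {
    x <- unlist(x)
    stats::setNames(suppressWarnings(as.numeric(x)), names(x))
  }
  for (s in c("componentLatenciesMS", "componentAmplitudesUV",
              "sharedAmplitudesUV"))
    pl[[s]] <- namedNum(pl[[s]])
  pl$sourcePosition <- suppressWarnings(as.numeric(unlist(pl$sourcePosition)))
  for (s in c("spacingMM", "csOffsetMM", "csAngleDeg", "anteriorLateAmpUV",
              "anteriorLateDelayMS", "componentWidthMS", "sharedWidthMS",
              "spatialDecayMM", "stimRateHz", "noiseSDuV", "noiseCornerHz",
              "latencyJitterMS", "corruptedChannelFraction", "sampleRateHz"))
    pl[[s]] <- suppressWarnings(as.numeric(pl[[s]]))
  pl$requireCrossing <- as.logical(pl$requireCrossing)
  do.call(simParams, pl)
}

#' Read a fixture bundle back
#'
#' @param dir bundle directory written by [writeSessionBundle()].
#' @return list with `recording`, `geometry`, `truth` and `params` (NULL if
#'   absent from the sidecar).
#' @export
readSessionBundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(dir, "signal.bin"), "rb")
  sig <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  con <- file(file.path(dir, "emg.bin"), "rb")
  emg <- readBin(con, "double", n = meta$n_samples, size = 8,
                 endian = "little")
  close(con)
  data <- matrix(sig, nrow = meta$n_channels)
  rec <- new("TrialRecording", data = data, emg = emg,
             sampleRate = meta$sample_rate_hz,
             triggers = as.integer(meta$triggers),
             channelIDs = meta$channel_ids)
  g <- meta$geometry
  geom <- new("GridGeometry", nRows = as.integer(g$rows),
              nCols = as.integer(g$cols), spacingMM = g$spacing_mm,
              apAxis = g$ap_axis,
              positions = {
                p <- as.matrix(g$positions_mm); colnames(p) <- c("x", "y"); p
              },
              csLine = {
                cs <- as.matrix(g$cs_line); colnames(cs) <- c("x", "y"); cs
              })
  truth <- NULL
  if (!is.null(g$region_labels))
    truth <- new("GroundTruth", regionLabels = g$region_labels,
                 csLine = csLine(geom),
                 corruptedChannels = as.integer(g$corrupted_channels),
                 trueLatencies = unlist(g$true_latencies_ms))
  params <- if (!is.null(meta$params)) .paramsFromList(meta$params)
  list(recording = rec, geometry = geom, truth = truth, params = params)
}

#' Write an SSEPTrace as CSV plus JSON sidecar
#'
#' CSV rows are channels, columns are time points (header row = time in
#' ms); the sidecar `<path>.json` records flavor, excluded channels, trials
#' averaged and sample rate.
#'
#' @param trace an [SSEPTrace-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeTraceCSV <- function(trace, path) {
  v <- traceValues(trace)
  df <- data.frame(channel = rowData(trace)$channel_id, v,
                   check.names = FALSE)
  colnames(df) <- c("channel", sprintf("%.6f", timeAxis(trace)))
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(flavor = traceFlavor(trace),
                  excluded_channels = excludedChannels(trace),
                  n_trials = nTrialsAveraged(trace),
                  sample_rate_hz = metadata(trace)$sample_rate_hz)
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' Read an SSEPTrace written by [writeTraceCSV()]
#'
#' @param path CSV file path (expects `<path>.json` next to it).
#' @return an [SSEPTrace-class].
#' @export
readTraceCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  v <- as.matrix(df[, -1, drop = FALSE])
  SSEPTrace(v, as.numeric(colnames(df)[-1]), flavor = side$flavor,
            excluded = as.integer(side$excluded_channels),
            nTrials = if (is.null(side$n_trials)) NA_integer_
                      else side$n_trials,
            sampleRate = if (is.null(side$sample_rate_hz)) NA_real_
                         else side$sample_rate_hz,
            channelIDs = as.character(df[[1]]))
}

#' Write grid geometry (and optional ground truth) as JSON
#'
#' Schema: `{rows, cols, spacing_mm, ap_axis, positions_mm[[x,y]...],
#' cs_line[[x,y]...], region_labels[...]}`.
#'
#' @param geometry a [GridGeometry-class].
#' @param path target file.
#' @param truth optional [GroundTruth-class].
#' @return `path`, invisibly.
#' @export
writeGeometryJSON <- function(geometry, path, truth = NULL) {
  writeLines(jsonlite::toJSON(.geometryToList(geometry, truth),
                              auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Read grid geometry JSON
#'
#' @param path file written by [writeGeometryJSON()].
#' @return list with `geometry` and (when labels are present) `truth`.
#' @export
readGeometryJSON <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geom <- new("GridGeometry", nRows = as.integer(g$rows),
              nCols = as.integer(g$cols), spacingMM = g$spacing_mm,
              apAxis = g$ap_axis,
              positions = {
                p <- as.matrix(g$positions_mm); colnames(p) <- c("x", "y"); p
              },
              csLine = {
                cs <- as.matrix(g$cs_line); colnames(cs) <- c("x", "y"); cs
              })
  truth <- NULL
  if (!is.null(g$region_labels))
    truth <- new("GroundTruth", regionLabels = g$region_labels,
                 csLine = csLine(geom),
                 corruptedChannels = as.integer(g$corrupted_channels %||%
                                                  integer()),
                 trueLatencies = unlist(g$true_latencies_ms) %||% numeric())
  list(geometry = geom, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
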