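#' @include geometry.R
NULL

## ---------------------------------------------------------------------------
## Forward simulator: grid sessions with known ground truth.
##
## The waveform model is a sum of unit-peak Gaussian bumps. The posterior
## (S1) template carries the physiological N20-P25-P30 complex; the anterior
## (M1) template carries the phase-reversed P20 and a later negativity.
## An optional "shared" P25/P30 complex, common to both sides of the CS,
## emulates the superimposition of anterior P20 and posterior P25 that makes
## raw amplitudes overlap across the sulcus in some patients.
## ---------------------------------------------------------------------------

#' Simulation parameters
#'
#' @slot gridRows,gridCols,spacingMM,apAxis,csOffsetMM,csAngleDeg grid layout
#'   and CS placement, see [gridGeometry()].
#' @slot requireCrossing error if the CS line misses the grid (set FALSE for
#'   the no-crossing scenario).
#' @slot sourcePosition (x, y) mm of the amplitude maximum (hand-knob-like
#'   source, posterior-lateral of the CS); NA = derived from the geometry.
#' @slot componentLatenciesMS named (N20, P20, P25, P30) peak centres in ms.
#' @slot componentAmplitudesUV named (N20, P20, P25, P30) peak heights in uV.
#' @slot anteriorLateAmpUV,anteriorLateDelayMS the anterior late negativity:
#'   amplitude and delay after P30.
#' @slot componentWidthMS Gaussian bump sigma (ms) of the region-specific
#'   components.
#' @slot sharedAmplitudesUV named (P25, P30) amplitudes of the common-mode
#'   complex added to both templates (0 = off).
#' @slot sharedWidthMS bump sigma (ms) of the common-mode complex.
#' @slot spatialDecayMM exponential length scale of amplitude fall-off with
#'   distance from the source.
#' @slot nTrials number of stimulation trials.
#' @slot stimRateHz stimulation rate (0.6 Hz standard protocol).
#' @slot noiseSDuV stationary RMS of the per-channel background noise (uV).
#' @slot noiseCornerHz spectral corner of the AR(1) background-noise model:
#'   ECoG background power is concentrated at low frequencies, falling off
#'   roughly as 1/f^2 above the corner. `Inf` gives white noise.
#' @slot latencyJitterMS per-trial latency jitter SD (shared across channels).
#' @slot corruptedChannelFraction fraction of channels replaced by
#'   high-variance noise.
#' @slot sampleRateHz sampling rate (2400 Hz standard).
#' @slot seed RNG seed.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    gridRows = "integer", gridCols = "integer", spacingMM = "numeric",
    apAxis = "character", csOffsetMM = "numeric", csAngleDeg = "numeric",
    requireCrossing = "logical", sourcePosition = "numeric",
    componentLatenciesMS = "numeric", componentAmplitudesUV = "numeric",
    anteriorLateAmpUV = "numeric", anteriorLateDelayMS = "numeric",
    componentWidthMS = "numeric", sharedAmplitudesUV = "numeric",
    sharedWidthMS = "numeric", spatialDecayMM = "numeric",
    nTrials = "integer", stimRateHz = "numeric", noiseSDuV = "numeric",
    noiseCornerHz = "numeric",
    latencyJitterMS = "numeric", corruptedChannelFraction = "numeric",
    sampleRateHz = "numeric", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  lat <- object@componentLatenciesMS
  amp <- object@componentAmplitudesUV
  need <- c("N20", "P20", "P25", "P30")
  if (!all(need %in% names(lat)) || !all(need %in% names(amp)))
    msg <- c(msg, "latencies and amplitudes must name N20, P20, P25, P30")
  if (!all(is.finite(amp)) || !all(is.finite(object@sharedAmplitudesUV)))
    msg <- c(msg, "all amplitudes must be finite")
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if ("N20" %in% names(lat) && (lat["N20"] < 17 || lat["N20"] > 25))
    msg <- c(msg, "N20 latency must lie in [17, 25] ms")
  if ("P30" %in% names(lat) && (lat["P30"] < 27 || lat["P30"] > 40))
    msg <- c(msg, "P30 latency must lie in [27, 40] ms")
  if (object@spatialDecayMM <= 0) msg <- c(msg, "spatialDecayMM must be > 0")
  if (object@stimRateHz <= 0 || object@sampleRateHz <= 0)
    msg <- c(msg, "rates must be positive")
  if (object@corruptedChannelFraction < 0 || object@corruptedChannelFraction >= 1)
    msg <- c(msg, "corruptedChannelFraction must lie in [0, 1)")
  if (object@noiseCornerHz <= 0)
    msg <- c(msg, "noiseCornerHz must be positive (Inf = white)")
  if (length(msg)) msg else TRUE
})

#' Create simulation parameters
#'
#' Defaults describe a 64-channel high-density grid (8 x 8, 5 mm pitch) over
#' the sensorimotor cortex, 0.6 Hz median-nerve stimulation sampled at
#' 2.4 kHz, a posterior N20-P25-P30 complex of 10/3/8 uV peaking at
#' 20/25/31 ms with 2 ms Gaussian bumps, the phase-reversed anterior P20
#' (6 uV), exponential spatial decay (25 mm) around a source
#' posterior-lateral of the CS, band-limited background noise of 1.5 uV RMS
#' (AR(1), ~70 Hz spectral corner; this is the background remaining in the
#' SSEP pass-band after 30 Hz high-pass filtering, a small fraction of the
#' broadband ECoG amplitude), 0.5 ms trial jitter, and 137 stimulation
#' trials (the mean trial count of the clinical sessions the simulator
#' emulates, see [clinicalTrialCounts()]).
#'
#' @param ... named overrides of any slot of [SimulationParams-class]
#'   (e.g. `gridRows = 8, gridCols = 4, nTrials = 60, seed = 7`).
#' @return a validated [SimulationParams-class] object.
#' @seealso [simPreset()] for named scenario presets.
#' @export
simParams <- function(...) {
  p <- list(
    gridRows = 8L, gridCols = 8L, spacingMM = 5, apAxis = "column",
    csOffsetMM = NA_real_, csAngleDeg = 0, requireCrossing = TRUE,
    sourcePosition = c(NA_real_, NA_real_),
    componentLatenciesMS = c(N20 = 20, P20 = 20, P25 = 25, P30 = 31),
    componentAmplitudesUV = c(N20 = 10, P20 = 6, P25 = 3, P30 = 8),
    anteriorLateAmpUV = 5, anteriorLateDelayMS = 2,
    componentWidthMS = 2,
    sharedAmplitudesUV = c(P25 = 0, P30 = 0), sharedWidthMS = 4,
    spatialDecayMM = 25,
    nTrials = 137L, stimRateHz = 0.6, noiseSDuV = 1.5, noiseCornerHz = 70,
    latencyJitterMS = 0.5, corruptedChannelFraction = 0,
    sampleRateHz = 2400, seed = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad))
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) {
    v <- ov[[nm]]
    if (nm %in% c("componentLatenciesMS", "componentAmplitudesUV",
                  "sharedAmplitudesUV")) {
      ## partial named overrides allowed
      p[[nm]][names(v)] <- v
    } else p[[nm]] <- v
  }
  p$gridRows <- as.integer(p$gridRows); p$gridCols <- as.integer(p$gridCols)
  p$nTrials <- as.integer(p$nTrials); p$seed <- as.integer(p$seed)
  do.call(new, c(list("SimulationParams"), p))
}

#' Named simulation presets
#'
#' * `"clean"` - the defaults of [simParams()]: clear phase reversal.
#' * `"overlap"` - raw amplitudes overlap across the CS: a strong shared
#'   P25/P30 complex (10/12 uV, broad 4 ms bumps) rides on a small
#'   anti-symmetric N20/P20 pair (2 uV), so the raw morphology is nearly the
#'   same on both sides (no visible phase reversal) while its rate of change
#'   still differs.
#' * `"no_crossing"` - the CS line lies beyond the anterior grid edge, so
#'   every channel is posterior (a grid that failed to cross the sulcus).
#'
#' @param preset preset name.
#' @param ... further overrides passed to [simParams()].
#' @return a [SimulationParams-class] object.
#' @export
simPreset <- function(preset = c("clean", "overlap", "no_crossing"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    clean = list(),
    overlap = list(
      componentAmplitudesUV = c(N20 = 2, P20 = 2, P25 = 0, P30 = 0),
      anteriorLateAmpUV = 0,
      sharedAmplitudesUV = c(P25 = 10, P30 = 12)
    ),
    no_crossing = list(csOffsetMM = -10, requireCrossing = FALSE)
  )
  do.call(simParams, c(base, list(...)))
}

#' Frozen validation-ensemble conditions
#'
#' The study conditions used by the package's ensemble validation (tests and
#' the acceptance script): an 8 x 4 grid (32 channels, 5 mm pitch) with the
#' anterior-posterior axis along the 8-electrode direction, so each grid
#' column is a clinical-style 1 x 8 strip, and 60 stimulation trials per
#' session (a scaled-down session length; other parameters at their
#' defaults).
#'
#' @param preset scenario preset, see [simPreset()].
#' @param seed session seed.
#' @return a [SimulationParams-class].
#' @export
validationParams <- function(preset = c("clean", "overlap", "no_crossing"),
                             seed) {
  simPreset(match.arg(preset), gridRows = 8, gridCols = 4, apAxis = "row",
            nTrials = 60, seed = seed)
}

.gauss <- function(t, mu, sigma) exp(-(t - mu)^2 / (2 * sigma^2))

## band-limited Gaussian background noise: AR(1) per channel with stationary
## SD `sd` and a spectral corner near `cornerHz` (power ~1/f^2 above it);
## cornerHz = Inf degenerates to white noise. Returns channels x samples.
.backgroundNoise <- function(nCh, nSamp, sd, cornerHz, fs) {
  if (sd <= 0) return(matrix(0, nCh, nSamp))
  if (!is.finite(cornerHz))
    return(matrix(rnorm(nCh * nSamp, 0, sd), nCh, nSamp))
  rho <- max(0, 1 - 2 * pi * cornerHz / fs)
  innov <- matrix(rnorm(nSamp * nCh, 0, sd * sqrt(1 - rho^2)), nSamp, nCh)
  t(unclass(stats::filter(innov, filter = rho, method = "recursive")))
}

#' Regional SSEP waveform template
#'
#' Evaluates the noiseless source waveform of a region on a time axis (ms
#' post-stimulus). The posterior template is
#' `-A_N20 g(t; N20) + A_P25 g(t; P25) + A_P30 g(t; P30)`, the anterior
#' template `+A_P20 g(t; P20) - A_late g(t; P30 + delta)`, with `g` a
#' unit-peak Gaussian bump; any shared common-mode complex is added to both.
#' The opposite polarity of the two templates at ~20 ms is the phase
#' reversal the clinical technique relies on.
#'
#' @param region `"anterior"` or `"posterior"`.
#' @param params a [SimulationParams-class].
#' @param timeMs time axis in ms post-stimulus (must reach 0-50 ms when used
#'   for session synthesis).
#' @return numeric waveform in uV per sample of `timeMs`.
#' @examples
#' p <- simParams()
#' t <- seq(0, 60, by = 1 / 2.4)
#' post <- ssepTemplate("posterior", p, t)
#' ant <- ssepTemplate("anterior", p, t)
#' c(posterior = post[which.min(abs(t - 20))], anterior = ant[which.min(abs(t - 20))])
#' @export
ssepTemplate <- function(region, params, timeMs) {
  lat <- params@componentLatenciesMS
  amp <- params@componentAmplitudesUV
  s <- params@componentWidthMS
  shared <- params@sharedAmplitudesUV["P25"] *
      .gauss(timeMs, lat["P25"], params@sharedWidthMS) +
    params@sharedAmplitudesUV["P30"] *
      .gauss(timeMs, lat["P30"], params@sharedWidthMS)
  w <- switch(region,
    posterior = -amp["N20"] * .gauss(timeMs, lat["N20"], s) +
      amp["P25"] * .gauss(timeMs, lat["P25"], s) +
      amp["P30"] * .gauss(timeMs, lat["P30"], s),
    anterior = amp["P20"] * .gauss(timeMs, lat["P20"], s) -
      params@anteriorLateAmpUV *
        .gauss(timeMs, lat["P30"] + params@anteriorLateDelayMS, s),
    stop("unknown region label: ", region)
  )
  unname(w + shared)
}

#' Spatial amplitude gain
#'
#' Exponential fall-off of the evoked amplitude with Euclidean distance from
#' the source position: `gain = exp(-d / decay)`, 1 at the source.
#'
#' @param channelPos numeric (x, y) in mm, or a channels x 2 matrix.
#' @param sourcePosition numeric (x, y) of the amplitude maximum.
#' @param spatialDecayMM decay length scale in mm (> 0).
#' @return gain(s) in (0, 1].
#' @export
spatialGain <- function(channelPos, sourcePosition, spatialDecayMM) {
  stopifnot(spatialDecayMM > 0)
  pos <- if (is.matrix(channelPos)) channelPos else matrix(channelPos, ncol = 2)
  d <- sqrt((pos[, 1] - sourcePosition[1])^2 + (pos[, 2] - sourcePosition[2])^2)
  exp(-d / spatialDecayMM)
}

## run code under a local RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a full stimulation session
#'
#' Generates a continuous grid recording: each channel carries its region's
#' template scaled by the spatial gain, repeated at every stimulation onset
#' with per-trial latency jitter, plus white noise. The EMG channel carries
#' baseline noise and a large single-sample artifact spike at every onset
#' (the 200 us stimulation pulse spans less than one sample at 2.4 kHz).
#' A requested fraction of channels is replaced by high-variance noise
#' (corrupted contacts). Fully reproducible given `params@seed`.
#'
#' @param params a [SimulationParams-class].
#' @return list with elements `recording` ([TrialRecording-class]),
#'   `geometry` ([GridGeometry-class]), `truth` ([GroundTruth-class]) and
#'   `params`.
#' @examples
#' ses <- simulateSession(simParams(gridRows = 4, gridCols = 4, nTrials = 5,
#'                                  noiseSDuV = 0, seed = 2))
#' ses$recording
#' @export
simulateSession <- function(params) {
  validObject(params)
  geom <- gridGeometry(params@gridRows, params@gridCols, params@spacingMM,
                       params@apAxis,
                       csOffsetMM = if (is.na(params@csOffsetMM)) NULL
                                    else params@csOffsetMM,
                       csAngleDeg = params@csAngleDeg)
  pos <- positionsMM(geom)
  csx <- mean(csLine(geom)[, 1])
  xr <- range(pos[, 1])
  crosses <- csx > xr[1] && csx < xr[2]
  if (params@requireCrossing && !crosses)
    stop("CS line lies outside the grid but a crossing was requested")
  labels <- regionsFromGeometry(geom)

  src <- params@sourcePosition
  if (anyNA(src))
    src <- c(min(csx + params@spacingMM, xr[2]), 0.6 * max(pos[, 2]))
  gains <- spatialGain(pos, src, params@spatialDecayMM)

  fs <- params@sampleRateHz
  nCh <- nrow(pos)
  pad <- 1.0                               # seconds before first / after last
  onsetsSec <- pad + (seq_len(params@nTrials) - 1) / params@stimRateHz
  nSamp <- ceiling((max(onsetsSec) + pad) * fs)
  onsets <- as.integer(round(onsetsSec * fs)) + 1L
  tplLen <- round(0.060 * fs)              # template support 0-60 ms
  tplOffsets <- (seq_len(tplLen) - 1) / fs * 1000

  .withSeed(params@seed, {
    jitter <- rnorm(params@nTrials, 0, params@latencyJitterMS)
    data <- .backgroundNoise(nCh, nSamp, params@noiseSDuV,
                             params@noiseCornerHz, fs)
    for (i in seq_len(params@nTrials)) {
      tj <- tplOffsets - jitter[i]
      segPost <- ssepTemplate("posterior", params, tj)
      segAnt <- ssepTemplate("anterior", params, tj)
      cols <- onsets[i]:(onsets[i] + tplLen - 1L)
      seg <- outer(gains, segPost)
      isAnt <- labels == "anterior"
      if (any(isAnt)) seg[isAnt, ] <- outer(gains[isAnt], segAnt)
      data[, cols] <- data[, cols] + seg
    }
    nCorrupt <- round(params@corruptedChannelFraction * nCh)
    corrupted <- if (nCorrupt > 0) sort(sample.int(nCh, nCorrupt)) else integer()
    if (nCorrupt > 0) {
      ## corrupted contacts carry noise far above any neural signal: 20x the
      ## background RMS, floored at 200 uV so the fault dwarfs the evoked
      ## response even on quiet recordings
      sdCorrupt <- 20 * max(params@noiseSDuV, 10)
      data[corrupted, ] <- .backgroundNoise(nCorrupt, nSamp, sdCorrupt,
                                            params@noiseCornerHz, fs)
    }
    emgBaseSD <- 5
    emg <- rnorm(nSamp, 0, emgBaseSD)
    emg[onsets] <- emg[onsets] + 50 * emgBaseSD
    rec <- new("TrialRecording", data = data, emg = emg, sampleRate = fs,
               triggers = onsets,
               channelIDs = sprintf("ch%02d", seq_len(nCh)))
    truth <- new("GroundTruth", regionLabels = labels,
                 csLine = csLine(geom),
                 corruptedChannels = as.integer(corrupted),
                 trueLatencies = params@componentLatenciesMS)
    list(recording = rec, geometry = geom, truth = truth, params = params)
  })
}

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(
    "SimulationParams: %d x %d grid @ %.0f mm, %d trials @ %.1f Hz, fs %.0f Hz\n",
    object@gridRows, object@gridCols, object@spacingMM, object@nTrials,
    object@stimRateHz, object@sampleRateHz))
  cat(sprintf("  noise %.1f uV, jitter %.2f ms, decay %.0f mm, seed %d\n",
              object@noiseSDuV, object@latencyJitterMS,
              object@spatialDecayMM, object@seed))
})
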