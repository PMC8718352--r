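# shared fixtures: sessions are expensive (continuous 2.4 kHz recordings),
# so build them once per run and cache in an environment

.cache <- new.env(parent = emptyenv())

cachedSession <- function(key, params) {
  if (is.null(.cache[[key]])) .cache[[key]] <- simulateSession(params)
  .cache[[key]]
}

# small clean session used across files: 8 x 4 grid, anterior-posterior along
# the row index (1 x 8 clinical strip orientation), scaled-down trial count
smallCleanParams <- function(seed = 3, ...) {
  simParams(gridRows = 8, gridCols = 4, apAxis = "row", nTrials = 20,
            seed = seed, ...)
}

# tiny noiseless session for exact round-trip checks
noiselessParams <- function(seed = 1, ...) {
  simParams(gridRows = 4, gridCols = 4, nTrials = 1, noiseSDuV = 0,
            latencyJitterMS = 0, seed = seed, ...)
}

cachedTrace <- function(key, session) {
  tkey <- paste0(key, "_trace")
  if (is.null(.cache[[tkey]]))
    .cache[[tkey]] <- preprocessRecording(session$recording)
  .cache[[tkey]]
}
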