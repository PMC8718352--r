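#' @include accessors.R
NULL

#' Detect stimulation triggers from the surface EMG
#'
#' The stimulation artifact dominates the EMG baseline, so onsets are taken
#' as threshold crossings of the absolute deviation from the median,
#' `|emg - median| > 8 * MAD`, collapsed with a refractory period of half
#' the inter-stimulus interval so one artifact yields one trigger.
#'
#' @param emg numeric EMG samples (uV).
#' @param sampleRateHz sampling rate.
#' @param stimRateHz nominal stimulation rate (default 0.6 Hz).
#' @return integer vector of onset sample indices, ascending.
#' @export
detectTriggers <- function(emg, sampleRateHz, stimRateHz = 0.6) {
  if (length(emg) < 2 / stimRateHz * sampleRateHz)
    stop("EMG shorter than two inter-stimulus intervals")
  dev <- abs(emg - median(emg))
  thr <- 8 * mad(emg)
  idx <- which(dev > thr)
  if (!length(idx)) stop("no stimulation detected")
  refractory <- round(0.5 / stimRateHz * sampleRateHz)
  keep <- integer(length(idx))
  n <- 0L
  last <- -Inf
  for (i in idx) {
    if (i - last > refractory) {
      n <- n + 1L
      keep[n] <- i
      last <- i
    }
  }
  keep[seq_len(n)]
}

#' Zero-phase high-pass filtering
#'
#' 2nd-order Butterworth high-pass applied forward and backward
#' (filtfilt), so the net phase shift is zero and the effective magnitude
#' response is the squared single-pass response. The 30 Hz default removes
#' slow drifts and DC while passing the fast SSEP components.
#'
#' @param x a [TrialRecording-class] (all data channels are filtered, the
#'   EMG is left untouched) or a channels x samples matrix / numeric vector.
#' @param sampleRateHz sampling rate; taken from the recording when `x` is a
#'   TrialRecording.
#' @param cutoffHz high-pass cutoff (must be below Nyquist).
#' @param order Butterworth order of the single pass.
#' @return object of the same kind as `x`, filtered.
#' @export
highpassZeroPhase <- function(x, sampleRateHz = NULL, cutoffHz = 30,
                              order = 2) {
  if (is(x, "TrialRecording")) {
    filt <- highpassZeroPhase(x@data, x@sampleRate, cutoffHz, order)
    return(new("TrialRecording", data = filt, emg = x@emg,
               sampleRate = x@sampleRate, triggers = x@triggers,
               channelIDs = x@channelIDs))
  }
  if (is.null(sampleRateHz)) stop("sampleRateHz is required")
  if (cutoffHz >= sampleRateHz / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoffHz / (sampleRateHz / 2), type = "high")
  nf <- min(3L * ceiling(sampleRateHz / cutoffHz), 1000L)
  if (is.matrix(x)) {
    out <- t(.filtfilt(bf, t(x), nf))
    dimnames(out) <- dimnames(x)
    out
  } else {
    .filtfilt(bf, matrix(x, ncol = 1), nf)[, 1]
  }
}

## single IIR pass y[n] = sum(b x) - sum(a y), a[1] = 1, applied column-wise
## (direct form via two C-level stats::filter calls on the whole matrix)
.iirPass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(rbind(matrix(0, nb - 1L, ncol(x)), x), filter = b,
                     method = "convolution", sides = 1)
  v <- v[nb:(nb - 1L + nrow(x)), , drop = FALSE]
  unclass(stats::filter(v, filter = -a[-1], method = "recursive"))
}

## forward-backward filtering with odd-reflection edge padding (the padding
## absorbs the filter transient; the two passes cancel the phase response);
## x is samples x channels
.filtfilt <- function(bf, x, nf) {
  n <- nrow(x)
  nf <- min(nf, n - 1L)
  refl <- function(i, anchor) 2 * x[rep(anchor, length(i)), , drop = FALSE] -
    x[i, , drop = FALSE]
  ext <- rbind(refl((nf + 1L):2L, 1L), x, refl((n - 1L):(n - nf), n))
  y <- .iirPass(bf$b, bf$a, ext)
  y <- .iirPass(bf$b, bf$a, y[nrow(y):1L, , drop = FALSE])
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(nf + 1L):(nf + n), , drop = FALSE]
}

#' Epoch a recording at the triggers and average
#'
#' Aligns the data to each stimulation onset (t = 0 at the trigger sample)
#' and averages over trials on the post-stimulus window, by default
#' `[10, 50)` ms. Epochs that would extend past the recording are dropped
#' and counted.
#'
#' @param recording a [TrialRecording-class].
#' @param triggers onset sample indices; defaults to the recording's stored
#'   triggers, or EMG detection when none are stored.
#' @param windowMs length-2 window in ms post-stimulus, inclusive-exclusive.
#' @return an [SSEPTrace-class] of flavor `"raw"`; the number of dropped
#'   epochs is in `metadata(trace)$n_dropped`.
#' @export
epochAverage <- function(recording, triggers = NULL, windowMs = c(10, 50)) {
  fs <- recording@sampleRate
  if (is.null(triggers)) {
    triggers <- if (length(recording@triggers)) recording@triggers
                else detectTriggers(recording@emg, fs)
  }
  if (!length(triggers)) stop("at least one trigger is required")
  k0 <- ceiling(windowMs[1] / 1000 * fs)
  k1 <- ceiling(windowMs[2] / 1000 * fs) - 1L
  offsets <- k0:k1
  nSamp <- ncol(recording@data)
  valid <- triggers + k0 >= 1L & triggers + k1 <= nSamp
  nDropped <- sum(!valid)
  triggers <- triggers[valid]
  if (!length(triggers)) stop("no valid epochs inside the recording")
  acc <- matrix(0, nrow(recording@data), length(offsets))
  for (tr in triggers)
    acc <- acc + recording@data[, tr + offsets, drop = FALSE]
  avg <- acc / length(triggers)
  tr <- SSEPTrace(avg, offsets / fs * 1000, flavor = "raw",
                  nTrials = length(triggers), sampleRate = fs,
                  channelIDs = recording@channelIDs)
  metadata(tr)$n_dropped <- nDropped
  tr
}

#' Savitzky-Golay smoothing of SSEP traces
#'
#' Least-squares local polynomial smoothing (degree 3 by default), which
#' smooths the trace without flattening its peaks: any polynomial input up
#' to the chosen degree is reproduced exactly.
#'
#' @param trace an [SSEPTrace-class].
#' @param polyorder polynomial degree.
#' @param windowLengthMs filter window in ms; converted to an odd sample
#'   count at the trace's sampling rate.
#' @param windowLengthSamples explicit window length in samples (odd,
#'   greater than `polyorder`); overrides `windowLengthMs`.
#' @return the smoothed trace (same flavor).
#' @export
smoothSavGol <- function(trace, polyorder = 3, windowLengthMs = 5,
                         windowLengthSamples = NULL) {
  tm <- timeAxis(trace)
  dt <- tm[2] - tm[1]                       # ms per sample
  if (is.null(windowLengthSamples)) {
    n <- round(windowLengthMs / dt)
    if (n %% 2 == 0) n <- n + 1L
  } else {
    n <- as.integer(windowLengthSamples)
    if (n %% 2 == 0) stop("window length must be odd")
  }
  if (n <= polyorder)
    stop("window length must exceed the polynomial order")
  if (n > ncol(trace)) stop("window longer than the trace")
  v <- traceValues(trace)
  sm <- t(apply(v, 1, function(row) signal::sgolayfilt(row, p = polyorder,
                                                       n = n)))
  dimnames(sm) <- dimnames(v)
  setTraceValues(trace, sm)
}

#' Detect corrupted channels by their outlying variance
#'
#' Corrupted contacts stand out through their large variance within the
#' 10-50 ms window. Channels whose log-variance has a robust z-score
#' (median/MAD) above the threshold are flagged.
#'
#' @param trace an [SSEPTrace-class] (at least 4 channels).
#' @param zThreshold robust z-score cutoff.
#' @return integer indices of the flagged channels (possibly empty).
#' @export
detectCorruptedChannels <- function(trace, zThreshold = 3.5) {
  v <- traceValues(trace)
  if (nrow(v) < 4L) stop("at least 4 channels are required")
  lv <- log(apply(v, 1, var) + .Machine$double.xmin)
  md <- median(lv)
  s <- mad(lv)
  z <- (lv - md) / max(s, .Machine$double.eps)
  unname(which(z > zThreshold))
}

#' Time derivative of an SSEP trace
#'
#' Central differences on interior points and one-sided differences at the
#' window edges, in uV/ms. The central scheme keeps peak latencies
#' unshifted.
#'
#' @param trace an [SSEPTrace-class] of flavor `"raw"` or `"zscored"`.
#' @return an [SSEPTrace-class] of flavor `"derivative"` (or
#'   `"zscored_derivative"`).
#' @export
derivativeTrace <- function(trace) {
  flavor <- switch(traceFlavor(trace),
    raw = "derivative",
    zscored = "zscored_derivative",
    stop("trace is already a derivative flavor"))
  v <- traceValues(trace)
  if (ncol(v) < 3L) stop("at least 3 timepoints are required")
  tm <- timeAxis(trace)
  dt <- tm[2] - tm[1]
  n <- ncol(v)
  d <- v
  d[, 2:(n - 1)] <- (v[, 3:n] - v[, 1:(n - 2)]) / (2 * dt)
  d[, 1] <- (v[, 2] - v[, 1]) / dt
  d[, n] <- (v[, n] - v[, n - 1]) / dt
  setTraceValues(trace, d, flavor = flavor)
}

#' Per-channel z-score normalization
#'
#' Normalizes each channel to zero mean and unit variance over the window,
#' retaining the waveform morphology while discarding the amplitude scale
#' (the feature used for spectral clustering). Channels with zero variance
#' cannot be normalized and are flagged as corrupted instead.
#'
#' @param trace an [SSEPTrace-class] of flavor `"raw"` or `"derivative"`.
#' @return an [SSEPTrace-class] of flavor `"zscored"` or
#'   `"zscored_derivative"`.
#' @export
zscoreTrace <- function(trace) {
  flavor <- switch(traceFlavor(trace),
    raw = "zscored",
    derivative = "zscored_derivative",
    stop("trace is already z-scored"))
  v <- traceValues(trace)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  zero <- sdv == 0
  sdv[zero] <- 1
  z <- (v - mu) / sdv
  z[zero, ] <- 0
  out <- setTraceValues(trace, z, flavor = flavor)
  if (any(zero)) {
    warning(sum(zero), " zero-variance channel(s) flagged as corrupted")
    out <- markExcluded(out, which(zero))
  }
  out
}

#' Full preprocessing chain for one session
#'
#' High-pass filters the continuous recording (zero phase), detects triggers
#' from the EMG when none are stored, epochs and averages on the 10-50 ms
#' window, Savitzky-Golay smooths, and flags corrupted channels.
#'
#' @param recording a [TrialRecording-class].
#' @param cutoffHz,filterOrder high-pass settings.
#' @param windowMs averaging window.
#' @param polyorder,windowLengthMs Savitzky-Golay settings.
#' @param zThreshold corrupted-channel threshold.
#' @return an [SSEPTrace-class] of flavor `"raw"` with corrupted channels
#'   marked excluded.
#' @export
preprocessRecording <- function(recording, cutoffHz = 30, filterOrder = 2,
                                windowMs = c(10, 50), polyorder = 3,
                                windowLengthMs = 5, zThreshold = 3.5) {
  filtered <- highpassZeroPhase(recording, cutoffHz = cutoffHz,
                                order = filterOrder)
  trace <- epochAverage(filtered, windowMs = windowMs)
  trace <- smoothSavGol(trace, polyorder = polyorder,
                        windowLengthMs = windowLengthMs)
  bad <- detectCorruptedChannels(trace, zThreshold = zThreshold)
  if (length(bad)) trace <- markExcluded(trace, bad)
  trace
}
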