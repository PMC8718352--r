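#' @include io-fixture.R
NULL

## ---------------------------------------------------------------------------
## Minimal EDF+C export/import of a TrialRecording: one 16-bit signal per
## electrode, one EMG signal, and one annotations signal carrying the
## stimulation onsets as time-stamped annotation lists (TALs). Records are
## 1 s long; the tail of the last record is zero-padded.
## ---------------------------------------------------------------------------

.edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too long: ", s)
  formatC(s, width = width, flag = "-")
}

.edfNum <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  .edfField(s, width)
}

#' Write a recording as EDF+C
#'
#' Electrode channels and the EMG become 16-bit EDF signals (physical units
#' uV, symmetric physical range per signal); stimulation triggers are
#' stored as "Stim" annotations in an EDF Annotations signal.
#'
#' @param recording a [TrialRecording-class].
#' @param path output file.
#' @param patientID,recordingID EDF header identification fields.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path, patientID = "X X X X",
                     recordingID = "Startdate 01-JAN-2026 X X X") {
  fs <- recording@sampleRate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sample rate per 1 s record")
  fs <- as.integer(round(fs))
  sig <- rbind(recording@data, EMG = recording@emg)
  labels <- c(recording@channelIDs, "EMG")
  nSig <- nrow(sig)
  nSamp <- ncol(sig)
  nRec <- as.integer(ceiling(nSamp / fs))
  annSamples <- 60L                       # 120 bytes of TAL space per record
  physMax <- apply(abs(sig), 1, max)
  physMax <- signif(pmax(physMax * 1.01, 1), 6)

  con <- file(path, "wb")
  on.exit(close(con))
  writeField <- function(x, width) writeChar(.edfField(x, width), con,
                                             nchars = width, eos = NULL)
  nsTotal <- nSig + 1L
  headerBytes <- 256L + 256L * nsTotal
  writeField("0", 8)
  writeField(patientID, 80)
  writeField(recordingID, 80)
  writeField("01.01.26", 8)
  writeField("00.00.00", 8)
  writeField(headerBytes, 8)
  writeField("EDF+C", 44)
  writeField(nRec, 8)
  writeField("1", 8)
  writeField(nsTotal, 4)
  allLabels <- c(labels, "EDF Annotations")
  for (l in allLabels) writeField(l, 16)
  for (i in seq_len(nsTotal)) writeField("", 80)              # transducer
  for (i in seq_len(nsTotal)) writeField(if (i <= nSig) "uV" else "", 8)
  for (i in seq_len(nsTotal))
    writeChar(if (i <= nSig) .edfNum(-physMax[i]) else .edfField("-1", 8),
              con, nchars = 8, eos = NULL)
  for (i in seq_len(nsTotal))
    writeChar(if (i <= nSig) .edfNum(physMax[i]) else .edfField("1", 8),
              con, nchars = 8, eos = NULL)
  for (i in seq_len(nsTotal)) writeField("-32768", 8)
  for (i in seq_len(nsTotal)) writeField("32767", 8)
  for (i in seq_len(nsTotal)) writeField("", 80)              # prefiltering
  for (i in seq_len(nsTotal))
    writeField(if (i <= nSig) fs else annSamples, 8)
  for (i in seq_len(nsTotal)) writeField("", 32)              # reserved

  trigSec <- (recording@triggers - 1L) / fs
  for (r in seq_len(nRec)) {
    i0 <- (r - 1L) * fs + 1L
    i1 <- min(r * fs, nSamp)
    for (s in seq_len(nSig)) {
      seg <- numeric(fs)
      seg[seq_len(i1 - i0 + 1L)] <- sig[s, i0:i1]
      ## exact inverse of the reader's affine map phys = f(dig)
      dig <- as.integer(round((seg + physMax[s]) / (2 * physMax[s]) * 65535
                              - 32768))
      dig <- pmax(pmin(dig, 32767L), -32768L)
      writeBin(dig, con, size = 2, endian = "little")
    }
    inRec <- trigSec[trigSec >= r - 1 & trigSec < r]
    tals <- c(sprintf("+%d\x14\x14", r - 1L),                 # record stamp
              sprintf("+%.6f\x14Stim\x14", inRec))
    raw <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0L))))
    if (length(raw) > 2L * annSamples)
      stop("too many annotations in one record")
    raw <- c(raw, raw(2L * annSamples - length(raw)))
    writeBin(raw, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+C file into a TrialRecording
#'
#' Understands the subset written by [writeEDF()]: ordinary 16-bit signals
#' plus an optional "EDF Annotations" signal, whose "Stim" annotations are
#' converted back to trigger sample indices. A signal labelled "EMG" is
#' mapped onto the EMG slot.
#'
#' @param path EDF file.
#' @return a [TrialRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # phys dim
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  isAnn <- labels == "EDF Annotations"
  chans <- which(!isAnn)
  out <- lapply(chans, function(i) numeric(nRec * nsamp[i]))
  names(out) <- labels[chans]
  annText <- character()
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        raw <- readBin(con, "raw", n = 2L * nsamp[i])
        annText <- c(annText, rawToChar(raw[raw != as.raw(0)]))
      } else {
        dig <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                       endian = "little")
        phys <- (dig - digMin[i]) * (physMax[i] - physMin[i]) /
          (digMax[i] - digMin[i]) + physMin[i]
        j <- match(i, chans)
        out[[j]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <- phys
      }
    }
  }
  ## parse "Stim" TALs: +<onset>\x14Stim\x14
  tals <- unlist(strsplit(paste(annText, collapse = ""), "\x14\x14",
                          fixed = TRUE))
  onsets <- numeric()
  for (chunk in tals) {
    parts <- unlist(strsplit(chunk, "\x14", fixed = TRUE))
    hits <- which(parts == "Stim") - 1L
    hits <- hits[hits >= 1L]
    onsets <- c(onsets, as.numeric(parts[hits]))
  }
  onsets <- sort(onsets[is.finite(onsets)])
  fs <- nsamp[chans[1]] / recDur
  emgIdx <- which(names(out) == "EMG")
  dataIdx <- setdiff(seq_along(out), emgIdx)
  data <- do.call(rbind, out[dataIdx])
  emg <- if (length(emgIdx)) out[[emgIdx]] else numeric(ncol(data))
  new("TrialRecording", data = data, emg = emg, sampleRate = fs,
      triggers = as.integer(round(onsets * fs)) + 1L,
      channelIDs = names(out)[dataIdx])
}
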