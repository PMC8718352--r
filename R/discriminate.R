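#' @include accessors.R
NULL

## normalize a labels argument (character vector or GroundTruth) to a
## character vector aligned with the trace channels
.resolveLabels <- function(labels, trace) {
  if (is(labels, "GroundTruth")) labels <- regionLabels(labels)
  if (length(labels) != nrow(trace))
    stop("labels must have one entry per trace channel")
  labels
}

#' Fisher discriminant profile between anterior and posterior channels
#'
#' For every time point, F(t) = (muA(t) - muP(t))^2 / (varA(t) + varP(t)),
#' where muA/muP are the means and varA/varP the n-1 sample variances of the
#' anterior and posterior channel groups. Large F marks the time points at
#' which the two sides of the central sulcus separate best. Excluded
#' channels never enter the statistics.
#'
#' @param trace an [SSEPTrace-class] (any flavor; the flavor is recorded in
#'   the profile).
#' @param labels per-channel region labels ("anterior"/"posterior"/
#'   "excluded") or a [GroundTruth-class].
#' @return a [FisherProfile-class].
#' @examples
#' tr <- SSEPTrace(rbind(c(1, 0), c(2, 0), c(3, 0), c(4, 0)),
#'                 timeMs = c(20, 30))
#' fp <- fisherProfile(tr, c("anterior", "anterior", "posterior", "posterior"))
#' fisherValues(fp)   # (1.5 - 3.5)^2 / (0.5 + 0.5) = 4 at 20 ms
#' @export
fisherProfile <- function(trace, labels) {
  labels <- .resolveLabels(labels, trace)
  labels[excludedChannels(trace)] <- "excluded"
  v <- traceValues(trace)
  a <- v[labels == "anterior", , drop = FALSE]
  p <- v[labels == "posterior", , drop = FALSE]
  if (nrow(a) < 2L || nrow(p) < 2L)
    stop("each class needs at least 2 channels for a defined variance")
  muA <- colMeans(a); muP <- colMeans(p)
  varA <- apply(a, 2, var); varP <- apply(p, 2, var)
  num <- (muA - muP)^2
  den <- varA + varP
  F <- ifelse(den > 0, num / den, ifelse(num == 0, 0, Inf))
  if (any(is.infinite(F)))
    warning("zero within-class variance with unequal means: F = Inf flagged")
  new("FisherProfile", F = as.numeric(F), muA = muA, muP = muP,
      varA = varA, varP = varP, tMs = timeAxis(trace),
      flavor = traceFlavor(trace))
}

## indices of simple local maxima / minima (interior points only)
.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}
.localMinima <- function(y) .localMaxima(-y)

#' Detect physiological SSEP peaks per channel
#'
#' The 1st N is the minimum of the trace in the 17-25 ms search window and
#' the 2nd P the maximum in 27-40 ms. Peak amplitude is trough-to-peak: the
#' height between the extremum and the nearest preceding local extremum of
#' opposite polarity inside the 10-50 ms window (the window-start value when
#' none exists). Extrema that sit on a search-window boundary without being
#' local extrema are flagged low-confidence. Intermediate peaks in 22-30 ms
#' (superimposed anterior P20 / posterior P25 activity) are located and
#' counted but marked as excluded from statistics.
#'
#' @param trace an [SSEPTrace-class] covering 10-50 ms (flavor raw or
#'   derivative).
#' @param labels optional per-channel region labels (annotated in the
#'   output).
#' @return a [S4Vectors::DataFrame] with one row per channel: latencies
#'   (ms), trough-to-peak amplitudes (uV), confidence flags, and the count
#'   of intermediate 22-30 ms peaks.
#' @export
detectPeaks <- function(trace, labels = NULL) {
  tm <- timeAxis(trace)
  v <- traceValues(trace)
  if (!is.null(labels)) labels <- .resolveLabels(labels, trace)
  one <- function(y) {
    selN <- which(tm >= 17 & tm <= 25)
    iN <- selN[which.min(y[selN])]
    nFlag <- if (iN %in% .localMinima(y)) "ok" else "boundary"
    prevMax <- .localMaxima(y)
    prevMax <- prevMax[prevMax < iN]
    refN <- if (length(prevMax)) y[max(prevMax)] else y[1]
    selP <- which(tm >= 27 & tm <= 40)
    iP <- selP[which.max(y[selP])]
    pFlag <- if (iP %in% .localMaxima(y)) "ok" else "boundary"
    prevMin <- .localMinima(y)
    prevMin <- prevMin[prevMin < iP]
    refP <- if (length(prevMin)) y[max(prevMin)] else y[1]
    inter <- union(.localMaxima(y), .localMinima(y))
    inter <- inter[tm[inter] >= 22 & tm[inter] <= 30]
    c(n1_latency_ms = tm[iN], n1_amp_uV = abs(y[iN] - refN),
      n1_boundary = as.numeric(nFlag == "boundary"),
      p2_latency_ms = tm[iP], p2_amp_uV = abs(y[iP] - refP),
      p2_boundary = as.numeric(pFlag == "boundary"),
      n_intermediate = length(inter))
  }
  res <- unname(t(apply(v, 1, one)))
  colnames(res) <- c("n1_latency_ms", "n1_amp_uV", "n1_boundary",
                     "p2_latency_ms", "p2_amp_uV", "p2_boundary",
                     "n_intermediate")
  col <- function(nm) unname(res[, nm])   # 1-row matrices re-attach names
  DataFrame(
    channel = rowData(trace)$channel_id,
    region = if (is.null(labels)) NA_character_ else labels,
    n1_latency_ms = col("n1_latency_ms"),
    n1_amp_uV = col("n1_amp_uV"),
    n1_flag = ifelse(col("n1_boundary") > 0, "boundary", "ok"),
    p2_latency_ms = col("p2_latency_ms"),
    p2_amp_uV = col("p2_amp_uV"),
    p2_flag = ifelse(col("p2_boundary") > 0, "boundary", "ok"),
    n_intermediate_22_30 = as.integer(col("n_intermediate")),
    excluded = rowData(trace)$excluded
  )
}

#' AUC between two score sets (Mann-Whitney, midrank ties)
#'
#' @param scoresA,scoresB numeric scores of the two classes.
#' @return list with `auc` (oriented so auc >= 0.5), `polarity` (which class
#'   scores higher under the winning orientation: "A" or "B") and
#'   `auc_raw` = P(score_A > score_B) + 0.5 P(equal).
#' @export
aucFromScores <- function(scoresA, scoresB) {
  nA <- length(scoresA); nB <- length(scoresB)
  if (nA == 0L || nB == 0L) stop("both classes must be non-empty")
  r <- rank(c(scoresA, scoresB))           # midranks handle ties
  aucRaw <- (sum(r[seq_len(nA)]) - nA * (nA + 1) / 2) / (nA * nB)
  if (aucRaw >= 0.5) list(auc = aucRaw, polarity = "A", auc_raw = aucRaw)
  else list(auc = 1 - aucRaw, polarity = "B", auc_raw = aucRaw)
}

#' ROC AUC of the anterior/posterior separation at one time point
#'
#' Uses the per-channel trace values at the time sample nearest `tMs` as
#' scores for the anterior-vs-posterior labelling and reports the
#' Mann-Whitney AUC, oriented so that AUC >= 0.5 (anterior and posterior
#' sign conventions differ between the N and P peaks; the winning polarity
#' is reported).
#'
#' @param trace an [SSEPTrace-class].
#' @param labels per-channel region labels or a [GroundTruth-class].
#' @param tMs time point in ms.
#' @return list with `auc`, `polarity` ("anterior_higher"/
#'   "posterior_higher"), `auc_raw` and `t_ms` (the snapped time).
#' @export
rocAucAtTime <- function(trace, labels, tMs) {
  labels <- .resolveLabels(labels, trace)
  labels[excludedChannels(trace)] <- "excluded"
  tm <- timeAxis(trace)
  i <- which.min(abs(tm - tMs))
  sc <- traceValues(trace)[, i]
  res <- aucFromScores(sc[labels == "anterior"], sc[labels == "posterior"])
  list(auc = res$auc,
       polarity = if (res$polarity == "A") "anterior_higher"
                  else "posterior_higher",
       auc_raw = res$auc_raw, t_ms = tm[i])
}

#' Paired t-test between two per-subject metrics
#'
#' Standard paired t-test on the differences. Degenerate inputs are handled
#' explicitly: identical vectors give t = 0, p = 1; constant nonzero
#' differences have zero variance and return an infinite t with a warning.
#'
#' @param valuesA,valuesB numeric vectors of equal length (>= 2).
#' @return list with `statistic`, `p.value`, `df` and `flag` ("ok",
#'   "zero_diff" or "zero_variance").
#' @export
pairedTTest <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB) || length(valuesA) < 2L)
    stop("inputs must have equal length >= 2")
  d <- valuesA - valuesB
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, p.value = 1, df = length(d) - 1L,
                  flag = "zero_diff"))
    warning("zero variance of differences: infinite t flagged")
    return(list(statistic = sign(mean(d)) * Inf, p.value = 0,
                df = length(d) - 1L, flag = "zero_variance"))
  }
  tt <- t.test(valuesA, valuesB, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), flag = "ok")
}
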