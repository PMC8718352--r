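#' @include accessors.R
NULL

#' Stimulation trial counts of the reference clinical sessions
#'
#' Per-patient stimulation trial counts of the eight intraoperative
#' median-nerve SSEP sessions the simulator emulates (over 100 trials are
#' typically delivered for reproducible cortical responses; one patient
#' received fewer).
#'
#' @return data.frame with columns patient, hemisphere, trials, state.
#' @examples
#' tc <- clinicalTrialCounts()
#' trialCountSummary(tc$trials)
#' @export
clinicalTrialCounts <- function() {
  read.csv(system.file("extdata", "clinical_trial_counts.csv",
                       package = "ssepcs"), stringsAsFactors = FALSE)
}

#' Mean and sample SD of a set of trial counts
#'
#' @param trials numeric vector of per-session trial counts.
#' @return named numeric: `mean`, `sd` (n-1 denominator).
#' @export
trialCountSummary <- function(trials) {
  c(mean = mean(trials), sd = sd(trials))
}
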