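---
title: "Delineating the central sulcus from SSEP grid recordings: methods and design"
author: "ssepcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating the central sulcus from SSEP grid recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssepcs)
```

## The problem

Median-nerve somatosensory evoked potentials (SSEPs) recorded from subdural
electrodes reverse polarity across the central sulcus (CS): postcentral (S1)
contacts show the classic N20 negativity followed by P25/P30 positivities,
while precentral (M1) contacts show the mirrored P20. Clinically this phase
reversal is read off strip electrodes by eye, which is sensitive to strip
placement and to patients in whom the raw amplitudes on the two sides of the
sulcus overlap. With a full electrode grid the same information can be
extracted without manual peak reading: the spatial amplitude field viewed as
a heat map outlines the sulcus, and unsupervised clustering of whole SSEP
waveforms separates anterior from posterior channels automatically.

`ssepcs` implements that pipeline end to end, together with a forward
simulator that generates grid sessions with known ground truth, so that
every stage is testable without patient recordings (which are not publicly
distributable in this setting).

## Pipeline

1. **Trigger detection.** The stimulation artifact dominates the bipolar
   surface EMG; onsets are threshold crossings of `|emg - median| > 8 * MAD`
   collapsed with a refractory period of half the inter-stimulus interval.
   The threshold and refractory rule are this package's operationalization;
   they are robust to baseline drift and to artifact ringing (a spike
   doublet yields one trigger).
2. **Zero-phase high-pass.** A 2nd-order Butterworth at 30 Hz applied
   forward and backward (`filtfilt` style), so peak latencies are not
   shifted and slow drift/DC is removed. The implementation runs the IIR
   recursion at C speed with odd-reflection edge padding; its interior
   output matches `signal::filtfilt` to ~1e-14 and its zero-lag and
   stop-band properties are unit-tested.
3. **Epoching and averaging** on the `[10, 50)` ms post-stimulus window
   (t = 0 at the trigger sample; 96 samples at 2.4 kHz). Epochs running
   past the recording are dropped and counted.
4. **Savitzky-Golay smoothing**, degree 3, 5 ms window (13 samples at
   2.4 kHz). The window length is a package default: it spans about six
   samples per side, enough to suppress residual averaging noise while a
   2 ms-wide evoked peak (FWHM ~4.7 ms) loses only a few percent of its
   height; cubic reproduction is exact by construction and unit-tested.
5. **Corrupted-channel rejection.** Channels whose log-variance over the
   window has a robust z-score (median/MAD) above 3.5. The exact clinical
   rule is not published; this is the standard robust-outlier convention
   and detects the simulator's 20x-variance corrupted contacts exactly.
6. **Trace flavors.** From the raw averaged trace the package derives the
   time derivative (central differences, uV/ms; one-sided at the window
   edges), the per-channel z-scored trace (zero mean, unit variance over
   the window, n-1 denominator) and the z-scored derivative. Zero-variance
   channels are flagged as corrupted rather than divided.

## Discriminative time points

For region-annotated channels the Fisher discriminant ratio

$$F(t) = \frac{(\mu_A(t) - \mu_P(t))^2}{\sigma_A^2(t) + \sigma_P^2(t)}$$

is computed per time point, with anterior/posterior class means and n-1
sample variances. The variance convention is not stated in the clinical
literature this follows; any consistent convention rescales F by a constant
when class sizes are fixed, so peak locations are unaffected. The profile's
global argmax and the windowed maxima in 17-25 ms (F_N20) and 27-40 ms
(F_P30) are reported. Per-channel physiological peaks are located as the
minimum in 17-25 ms (1st N) and the maximum in 27-40 ms (2nd P), with
trough-to-peak amplitudes measured against the nearest preceding local
extremum of opposite polarity (window-start value when none exists);
extrema that sit on a search boundary without being local extrema are
flagged low-confidence. Intermediate 22-30 ms peaks (superimposed anterior
P20 / posterior P25 activity) are located and counted but excluded from
statistics. Separation quality at any time point is quantified by the
Mann-Whitney AUC with midrank ties, reported as `max(AUC, 1 - AUC)` plus
the winning polarity, because the sign convention flips between the N and P
peaks.

## Spectral clustering

Channel waveforms (z-scored, so morphology rather than amplitude drives the
grouping) are compared by the Gaussian affinity

$$W_{ij} = \exp\!\left(-\frac{\lVert x_i - x_j \rVert^2}{2\sigma^2}\right),
\qquad \sigma = 2,$$

and the random-walk normalized Laplacian $L = I - D^{-1}W$,
$D_{ii} = \sum_j W_{ij}$, is decomposed via its symmetric equivalent
$I - D^{-1/2} W D^{-1/2}$ (numerically stable; eigenvalues identical,
eigenvectors mapped back by $D^{-1/2}$). Tiny negative eigenvalues above
-1e-10 are clipped to zero. The number of clusters k is the position of the
largest successive eigengap among the first five ascending eigenvalues
(k_max = 4); when the two largest gaps differ by less than `gapFloor`
(default 0.05) the tie breaks toward the smaller k, which operationalizes
the "elbow" reading of the spectrum. k = 1 is meaningful: it is the
signature of a grid that did not cross the sulcus (no phase reversal, one
waveform family). For k >= 2, k-means runs on the entries of the
second-smallest eigenvector — a 1-D embedding — with deterministic
quantile seeding plus 50 seeded random restarts; cluster ids are
renumbered by ascending center so results are reproducible, and the
eigenvector's sign is canonicalized. For two clusters, regions are
assigned either by ground truth (the accuracy-maximizing permutation of
the two possible mappings, accuracy = 100 x correct / total) or, without
ground truth, by polarity: the cluster whose mean trace is more negative
in 17-25 ms is posterior (the N20 side).

The electrode-size study reruns the clustering on every 1 x N strip running
along the anterior-posterior axis, every adjacent 2 x N pair, and the full
grid. Subsets with fewer than three usable channels are skipped. Subsets
that return k != 2 cannot be mapped to regions and are scored as the
majority-class fraction — a deliberate convention (the sources this
follows do not state one) that penalizes a single-cluster call on a strip
that does cross the sulcus.

## The forward simulator

`simulateSession()` produces a continuous multichannel recording at 2.4 kHz
with 0.6 Hz stimulation, an EMG channel carrying a one-sample artifact
spike per stimulus (a 200 us pulse spans less than one sample), per-trial
conduction jitter (SD 0.5 ms, shared across channels), optional corrupted
channels (20x background RMS, floored at 200 uV so a faulty contact dwarfs
any neural signal), and known ground truth (region labels, CS
line, component latencies).

Waveforms are sums of unit-peak Gaussian bumps (sigma 2 ms): the posterior
template `-A_N20 g(t; 20) + A_P25 g(t; 25) + A_P30 g(t; 31)` with
amplitudes 10/3/8 uV, the anterior template `+A_P20 g(t; 20) - A_late
g(t; 33)` with 6/5 uV. The clinical sources describe SSEP morphology only
through peak latencies and polarities; the Gaussian-bump shape is this
package's modeling choice — smooth, latency-preserving under symmetric
filtering, and analytically checkable — not an empirical claim about SSEP
generators. Amplitude decays as `exp(-d / 25 mm)` with distance from a
source placed posterior-lateral of the CS (the hand-knob pattern); over a
35 mm grid the weakest channel still retains ~38% of the source amplitude,
matching grids on which every contact shows recognizable SSEP morphology.

Background noise is band-limited Gaussian noise (AR(1) with a ~70 Hz
spectral corner, stationary RMS `noiseSDuV`, default 1.5 uV). Two points
matter here. First, the default is the background remaining *in the SSEP
pass-band after the 30 Hz high-pass*: broadband ECoG runs to tens of
microvolts, but its power spectrum is steep and only a few microvolts
survive above 30 Hz, and averaging over 100+ trials — the entire point of
the clinical protocol — divides that by another order of magnitude, which
is what makes averaged SSEP traces look nearly noise-free. Second, the
spectral corner matters: white noise at 2.4 kHz would put two orders of
magnitude more power into the high-frequency band that the time-derivative
trace amplifies, selectively breaking the derivative flavor — an artifact
of unrealistic noise, not a property of the method. `noiseCornerHz = Inf`
restores white noise for experiments.

The default trial count is 137, the mean of the reference clinical
sessions (`clinicalTrialCounts()`; clinical practice delivers over 100
trials so that averaged responses are reproducible).

Scenario presets (`simPreset()`):

* `"clean"` — the defaults: clear phase reversal, every channel with
  usable averaged SNR.
* `"overlap"` — a strong shared P25/P30 complex (10/12 uV, broad 4 ms
  bumps) common to both sides rides on a small anti-symmetric N20/P20 pair
  (2 uV). Raw morphologies on the two sides become nearly identical (the
  superimposition that blurs phase reversal in some patients): raw
  z-scored waveforms correlate at ~0.99 across the sulcus, the affinity
  graph merges into one cluster and raw clustering fails, while the
  derivative — which weights the fast anti-symmetric components 4x more
  heavily relative to the broad shared ones — still separates the two
  sides. This is the regime where the derivative trace outperforms the
  raw trace.
* `"no_crossing"` — the CS line lies beyond the grid edge; all channels
  are posterior and clustering should return k = 1.

### What the simulator does and does not emulate

It reproduces the features the pipeline's contracts depend on: grid
geometry and spacing, stimulation timing and EMG artifacts, post-stimulus
component structure with phase reversal, spatial amplitude decay, trial
jitter, band-limited background noise, corrupted contacts. It does not
model dipole orientation or volume conduction (amplitudes decay
isotropically from a point source), spatially correlated background
activity, cortical geometry (the CS is a straight or tilted line), awake
vs. sedated physiology, or latency differences across subjects' arm
lengths. Passing tests on simulated sessions therefore validate the
algorithmic contracts — not clinical performance on patient data.

## Problem sizes and numerical choices

Validation ensembles use an 8 x 4 grid (32 channels, 5 mm pitch) with the
anterior-posterior axis along the 8-electrode direction — each grid column
is then a clinical-style 1 x 8 strip — and 60 trials per session (one to
two minutes of recording at 0.6 Hz), 20 seeds per condition. These sizes
keep a full ensemble run in the minutes range while staying inside the
regime the defaults describe; single-session examples use the defaults.

Degenerate inputs are handled explicitly rather than left to numerics:
zero-variance channels are flagged, not divided; a constant second
eigenvector falls back to k = 1 with a warning; k-means falls back to a
deterministic largest-gap cut of the sorted 1-D embedding if every
restart degenerates; affinity matrices are symmetrized and the
constant-eigenvector eigenvalue clipped at zero; heat-map interpolation is
exact at electrodes (piecewise-bilinear on the lattice, with excluded
contacts' nodes filled from neighbours) and falls back to 1-D linear
interpolation for collinear strips.

## Known limitations

* The clustering regime depends on averaged-trace SNR: when background
  noise swamps the weakest channels' averaged waveforms, the affinity
  graph fragments and the eigengap returns k != 2. This mirrors clinical
  reality (poorly placed or low-SNR grids defeat phase-reversal reading)
  and is why k = 1 is reported as a meaningful "no crossing detected"
  outcome rather than an error.
* sigma = 2 is the field's value for z-scored traces of this length;
  `sigmaSweep()` exposes the knob but no automatic selection is attempted.
* The EDF+ writer/reader supports the subset this package produces
  (EDF+C, 16-bit, one annotation stream); it is not a general EDF library.
* Heat maps are 2-D grid renderings; no MRI co-registration or 3-D
  cortical surface fusion.

## A worked example

```{r example, eval = FALSE}
ses <- simulateSession(simParams(gridRows = 8, gridCols = 4, apAxis = "row",
                                 nTrials = 60, seed = 7))
trace <- preprocessRecording(ses$recording)
fp <- fisherProfile(trace, ses$truth)
discriminativePeaks(fp)

der <- derivativeTrace(trace)
res <- assignRegions(spectralCluster(der, sigma = 2, seed = 7), der,
                     ses$truth)
res
resampleGrids(der, ses$geometry, ses$truth, seed = 7)$summary
```

The vignette leaves the chunk unevaluated to keep package builds light;
the same sequence is exercised (with assertions) by the test suite, and
`scripts/acceptance.R` reruns the full ensemble study from scratch.
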