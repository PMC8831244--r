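---
title: "Methods: models, conventions and design choices"
author: "SensorPipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SensorPipelines)
```

SensorPipelines analyses fluorescence recordings from genetically encoded
GPCR-based neuropeptide sensors — intensiometric indicators built from a
receptor and a circularly permuted GFP, whose brightness reports ligand
binding. The package covers the full analysis chain used with such
sensors: in vitro dose-response and activation-kinetics quantification,
in vivo fiber photometry around optogenetic and behavioural events,
treadmill locomotion bouts, sleep-state transitions, and two-photon
cortical imaging with spatial microdomain (ROI) analysis. This vignette
documents the models, the numerical conventions, and the design choices
made where published descriptions leave the details open.

Throughout the package, time is in seconds, analysis windows are
half-open `[start, end)` unless an operation's definition requires
inclusive edges, pixel coordinates are `(row, col)` pairs (1-based, as is
natural in R), and every "s.d." is the sample (n − 1) standard deviation
— published method descriptions rarely state the convention, and the
sample form is the estimator every mainstream tool computes.

## Trace operations

**dF/F0.** The sensor response is
$\Delta F/F_0 = (F(t) - F_0)/F_0$, with $F_0$ the mean fluorescence over
a baseline specification: either an explicit window or the *n* samples
immediately before an event. The in vitro convention is the ten time
points immediately before ligand addition (`computeDff(trace, nPoints =
10, eventTime = ...)`). Whether those ten points are raw frames or binned
samples when acquisition rates differ is not fixed by the published
description, so the baseline is fully parameterised; the default treats
them as samples of whatever trace is supplied. A non-positive baseline
mean is an error, never a silent NaN: dF/F0 is meaningless without a
positive reference.

**Binning.** `binTrace` averages samples into fixed-width bins (100 ms
for all in vivo analyses) and *drops* a trailing partial bin. Averaging a
short final bin would give it a different variance than its neighbours
and bias anything computed downstream; dropping it loses at most one bin
width of data.

**Detrending.** `detrendLinearMedian` subtracts the straight line through
the medians of the first and last 30 s of the window (evaluated at the
window centers). Medians make the anchors robust to transients near the
window edges; a full linear regression would let a large mid-window
response tilt the fitted line.

**z-scoring.** `zscoreBaseline` computes
$z(t) = (x(t) - \mathrm{median}(b)) / \mathrm{sd}(b)$ over a stated
baseline window. The published wording ("divided by the s.d. of the
median baseline value") is ill-defined for a scalar median; the only
self-consistent reading — the s.d. of the baseline-window values, with
the median as the centre — is what the package implements. A zero
baseline s.d. raises an explicit degenerate-baseline error.

**Savitzky–Golay smoothing.** `savgolSmooth` uses `signal::sgolayfilt`
with the window length in seconds (4 s in the photometry pipeline,
rounded to an odd number of samples) and polynomial order 3 — a common
default; published descriptions state only the length. A one-sample
window is the identity.

## Kinetics and dose-response fits

**One-phase exponential.** `fitExpAssociation` fits
$y(t) = \mathrm{offset} + A\,(1 - e^{-t/\tau})$ (rise) or
$y(t) = \mathrm{offset} + A\,e^{-t/\tau}$ (decay) by Levenberg–Marquardt
least squares (`minpack.lm::nlsLM`). Starting values come from the data:
the offset from the mean of the 5% of samples nearest the asymptote, the
amplitude from the start-to-end excursion, and $\tau$ from the time to
63% of that excursion; $\tau$ is bounded in $(0, 10 \times$ window
duration$]$. Non-convergence and flat input are reported through a
`converged` flag together with $R^2$ — never as a silent NaN and never
as an error, because single bad trials must not abort a batch analysis.

**Four-parameter logistic.** `fit4PL` fits
$y = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) / (1 +
(\mathrm{EC}_{50}/x)^{h})$ on $\log_{10}$ dose, which makes the problem
well-scaled across the decades of a titration. Zero-dose points are
mapped to a pseudo-dose two decades below the smallest nonzero dose (a
finite plotting/fitting position for the blank). The starting Hill slope
takes the sign of the dose-response correlation, so inverse (decreasing)
curves converge to a negative slope rather than failing. With
`weighting = "relative"` the fit minimises relative (1/y²-weighted)
residuals, the appropriate scheme when errors are proportional to the
response, as they are in fluorescence titrations; the default remains
ordinary least squares.

## Fiber-photometry trial pipeline

`analyzeStimTrial` reproduces the published optogenetic trial analysis:
extract `[onset − 30 s, onset + 90 s)`, bin to 100 ms, Savitzky–Golay
filter, median-anchored linear detrend, z-score against the 10 s before
train onset, then take the peak z during the laser-on period (edges
inclusive at bin resolution). The rise is fitted from onset to
onset + 10 s after a 4-s Savitzky–Golay pass on that window; the decay is
fitted from train offset to the post-offset minimum, also smoothed by
default (the published decay windows were "smoothed and fitted as
above"). One wording note: the published text calls the trial window
"130-s" while defining it as 30 s before plus 90 s after onset; the
package follows the defining 30/90 specification (120 s).

"Fits that were too poor were excluded" comes with no criterion; the
package excludes a trial when either fit fails to converge or has
$R^2 < 0.5$, and the threshold is a parameter (`minR2`). A perfectly
flat, noise-free trial window has no baseline variability to z-score
against; it is reported as peak z = 0 with degenerate, excluded fits.

For sleep data, `stateTransitionDeltas` quantifies each state transition
as the unsigned range (max − min) of dF/F0 over the ±15 s around the
transition. The published wording is ambiguous between one symmetric
window and a pre/post pair; the single-window range is the default
because it is what "difference … between maximum and minimum of the 15-s
time point before and after the state transition" computes when read as
one interval, and a two-window variant (|mean post − mean pre|) is
available via `method = "twoWindow"`. Transitions closer than 15 s to a
trace edge are skipped with a warning.

## Locomotion

The rotary encoder emits one state change per degree of rotation.
`detectRunBouts` implements the published criterion: a bout onset is the
first state change after a 1-s window containing at most one change,
provided the following 5 s contain at least 65 changes. The published
geometry states "around 200 mm" per state change, which is inconsistent
both with the 11-cm wheel radius (2π × 110 mm / 360 ≈ 1.92 mm per
degree) and with the printed equivalence "65 state changes (13 cm)";
the package treats it as a typo for 2.00 mm, which reconciles the
criterion exactly (65 × 2.0 mm = 13 cm), and exposes `mmPerChange` as a
parameter. Candidate onsets are evaluated on raw event times (binning is
only for speed traces), and after a detected onset, detection is
suppressed for the 5-s counting window so one run is not counted twice.
Bout metrics (peak speed, peak z-scored fluorescence) are taken from the
2.5–5 s window after onset, and `correlateBoutPeaks` regresses
fluorescence peaks on speed peaks with the regression F-test.

## Two-photon pipeline

`fovDffTrace` treats each frame as a single ROI: $F(t)$ is the per-frame
pixel mean and $F_0$ the median of $F(t)$ over the anesthetized period
(the first minute of imaging). `findMostActiveMinute` scans minutes 3–6
with a moving window of $n = \mathrm{round}(60 \times$ frame rate$)$
frames advancing one frame per step, and selects the window with the
highest mean per-frame spatial s.d. (ties go to the earliest window).
The published description uses "the last minute of imaging" in one
sentence and "the 1 min of imaging with highest variance" in the next;
the package uses the most-active minute for both the binarization window
and its statistics — the self-consistent reading — and any explicit
window can be passed instead.

**Binarization.** Over the selected window,
$b(i,j,t) = 1$ iff $f(i,j,t) > \mathrm{median}_t f + \mathrm{sd}_t f$,
with strictly-greater comparison so a constant pixel (zero s.d.) is
never marked active. Because median and s.d. transform consistently, the
binarized movie is exactly invariant to any positive affine rescaling of
the raw intensities.

**Smoothing and deconvolution.** Each binarized frame is smoothed with a
2-D Gaussian (σ = 2 px), giving values in [0, 1], then deconvolved by
Richardson–Lucy iteration with a 39 × 39 px Gaussian point-spread
function of σ = 20 px (50 µm × 50 µm at 1.27 µm/px). The referenced
implementation's documented default of 10 iterations is used and is
configurable. Convolutions are FFT-based with circular boundary
(`EBImage::filter2`), under which the all-zero and uniform fields are
exact fixed points of the iteration; the symmetric kernel guarantees no
spatial shift.

**ROI identification.** Percentile bands are computed on the pixel
distribution pooled across all supplied deconvolved projections
(deconvolved values are comparable across fields of view), using
linear-interpolation (type 7) percentiles; band membership is closed at
the lower bound and open at the upper: active `[p70, p100]`, inactive
`[p5, p69)`, excluded `< p5` (perpendicular blood vessels). ROI
placement, unspecified in the published description, is greedy and
deterministic: repeatedly take the highest-valued uncovered in-band
pixel as a center and accept the circle (default diameter 12 px) if it
lies fully inside the image, overlaps no accepted ROI, and satisfies the
class constraint — an active ROI may contain no excluded pixel (it
"contains" the active band by construction of its center), while an
inactive ROI must consist entirely of sub-p70, non-excluded pixels so
that it is genuinely inactive. When the qualifying area cannot host the
requested 10 + 10 circles, the shortfall is returned with a warning
rather than padded. The printed gloss "12 pixels, 20.4 µm" is internally
inconsistent with 1.27 µm pixels (12 px = 15.24 µm); the diameter
defaults to the printed 12 px and is a parameter. ROI traces for
`roiCorrelationAnalysis` are per-frame means of the *raw* movie over the
window (the published heat maps show raw fluorescence), and class
summaries are means of off-diagonal Pearson correlations, with pairs
involving constant traces reported as missing.

## Line-scan kinetics

Dual-channel 550-Hz line scans resolve sub-second activation.
`classifyMembranePixels` thresholds the fractional green-channel change
between a pre- and post-ligand window; the threshold (0.5) is a
documented default, as no value is published. `dyeOnsetLatency` measures
the red (dye) channel's time from the last baseline-level sample to 85%
of its maximal change, with baseline the mean of the first 100 ms;
trials at or above 50 ms are rejected — slow solution exchange would
contaminate the sensor kinetics. `fitPixelTaus` low-pass filters each
membrane pixel (zero-phase 4th-order Butterworth, 20 Hz cutoff at
550 Hz; no published cutoff, so it is a parameter) and fits the
one-phase association from the dye arrival. Two numerical details
matter: the trace is reflectively padded before zero-phase filtering,
because unpadded `filtfilt` edge transients measurably bias τ via the
plateau end of the trace; and the first 50 ms after arrival are excluded
from the fit (`fitDelay`) to skip the filter's transition band around
the response onset — a shifted fit origin leaves an exponential's time
constant unchanged, so this costs nothing.

## Synthetic data

Every input modality has a seeded generator whose *defaults are the
study conditions*: photometry at 400 Hz with 30-s trains, rise
τ = 6.77 s and decay τ = 16.31 s, noise 10% of the response amplitude
and a slow linear drift; line scans at 550 Hz with τ = 0.596 s, a 9-fold
dynamic range and a fast red-dye step; titrations with EC50 = 75 nM,
Hill slope 1, 8 log-spaced doses over 4 decades and 10% multiplicative
noise; encoder streams built from bout schedules around the
65-changes-in-5-s criterion; hypnograms with wake/NREM at a common
dF/F0 level and REM lower by a configurable drop; movies of 128 × 128 px
at 4.9 Hz and 1.27 µm/px over 7 min, with anesthesia off at 1 min, a
sigmoidal global wake ramp (ground truth for the first-vs-last-minute
difference), dark vessel stripes, Poisson-like noise (Gaussian with
variance proportional to the mean — a dependency-light approximation to
detector statistics), and circular hotspots sharing one latent activity
course.

Two generator choices deserve their rationale on record. First, the
hotspot latent course is a train of ~2-s square release transients, one
per ~6 s, with amplitudes following a Gaussian envelope that peaks after
the wake ramp has plateaued. The ~1/3 duty cycle is deliberate: the
binarization marks pixels whose values exceed their temporal
median + s.d., so hotspot pixels must be elevated clearly more often
than the ~16% rate at which Gaussian noise alone crosses that threshold,
yet less than half the time (otherwise the median itself shifts into the
active level and the hotspot darkens in the projection). Sparse tall
bursts — however physiological they might look — invert the pipeline's
contrast, which is a property of the published binarization rule, not of
this implementation. Second, hotspots occupy roughly a fifth of the
frame: the active band is by definition the top 30% of pooled pixels, so
if hotspots (plus their deconvolution halo) cover much more than that,
hotspot edges spill into the "inactive" band and inactive ROIs inherit
the shared signal.

One global seed drives everything through a documented splitting scheme
(`splitSeed(seed, index)`, fixed indices per stream); identical seed and
parameters give bit-identical output, and generation never perturbs the
caller's RNG state.

What the generators do *not* emulate: photobleaching, motion artifacts
(inputs are assumed registered), hemodynamic contamination, spectral
crosstalk, non-uniform sensor expression, and real vigilance-state
statistics beyond dwell times. Tests passing on these simulations
demonstrate that the pipelines recover known ground truth under the
stated noise models — not that they are robust to every artifact of real
recordings.

## Problem sizes in the test-suite

The unit and property tests run the full two-photon pipeline on
72 × 72 px movies at 2 Hz over 6 min with five hotspots (~19% coverage)
and five ROIs per class — the same geometry as the study-condition
defaults, scaled so that a hundred seeded replicates remain a
few-minutes computation; the package-default 128-px, 4.9-Hz movie is
exercised end to end in the ROI-count and pipeline-driver tests.
Recovery runs use 50 seeded trials (photometry, line scans) and 100
seeded titrations, matching the sizes at which the corresponding
published estimates are quoted.

## Known limitations

* Richardson–Lucy uses circular boundary conditions; structure within
  half a kernel of the frame edge can alias across it. The published
  MATLAB reference pads edges differently, so per-pixel agreement near
  borders is not expected (band percentiles and ROI placement are
  robust to this).
* `signal::sgolayfilt` applies polynomial edge handling; the first and
  last half-window of a smoothed trace are fitted, not convolved.
* The greedy ROI placement is deterministic but not optimal; it can
  return fewer than the requested ROIs on fragmented bands where an
  optimal packing would fit them.
* Exponential fits assume a single kinetic component; multi-phasic
  responses converge to a weighted compromise with a lower $R^2$ rather
  than being detected as such.
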