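# SensorPipelines

Analysis pipelines for fluorescence recordings from genetically encoded
GPCR-based neuropeptide sensors — intensiometric indicators (receptor +
circularly permuted GFP) whose brightness reports extracellular peptide
levels, such as orexin sensors. The package is aimed at labs that
characterise such sensors in vitro and deploy them in vivo with fiber
photometry and two-photon imaging, and at anyone who wants the full
published analysis chain as tested, reusable R functions rather than
one-off scripts.

## What it computes

* **Trace operations** — ΔF/F₀ = (F(t) − F₀)/F₀ with an n-point
  pre-ligand baseline (`computeDff`), 100-ms binning (`binTrace`),
  Savitzky–Golay smoothing (`savgolSmooth`), median-anchored linear
  detrending (`detrendLinearMedian`), baseline z-scoring
  (`zscoreBaseline`).
* **Kinetics** — one-phase exponential association/decay
  y(t) = offset + A·(1 − e^(−t/τ)) fitted by Levenberg–Marquardt
  (`fitExpAssociation`), and the four-parameter logistic
  y = bottom + (top − bottom)/(1 + (EC₅₀/x)^h) on log₁₀ dose
  (`fit4PL`).
* **Photometry events** — the optogenetic trial pipeline
  (bin → smooth → detrend → z-score → laser-on peak, rise and decay
  fits; `analyzeStimTrial`), behavioural event comparisons
  (`eventLockedComparison`), sleep-state transition amplitudes from
  hypnograms (`stateTransitionDeltas`, `stateMeanDff`).
* **Locomotion** — rotary-encoder speed traces (`encoderToSpeed`),
  run-bout detection by the ≥65-state-changes-in-5-s criterion
  (`detectRunBouts`), bout-aligned peak metrics and their regression
  (`boutMetrics`, `correlateBoutPeaks`).
* **Two-photon microdomains** — field-of-view ΔF/F₀ against the
  anesthetized-period median (`fovDffTrace`), most-active-minute
  selection (`findMostActiveMinute`), pixelwise binarization
  b(i,j,t) = 1 iff f > medianₜ + s.d.ₜ (`binarizeWindow`), Gaussian
  smoothing + Richardson–Lucy deconvolution (`smoothAndDeconvolve`),
  percentile-band circular ROI identification (`identifyRois`) and
  pairwise Pearson correlation analysis (`roiCorrelationAnalysis`);
  `twoPhotonRoiPipeline` chains them.
* **Line-scan kinetics** — membrane-pixel classification, red-dye
  arrival gating (85% rise < 50 ms) and per-pixel τ fitting at 550 Hz
  (`classifyMembranePixels`, `dyeOnsetLatency`, `fitPixelTaus`).
* **Synthetic data** — seeded generators for every input modality with
  ground truth in the metadata (`genPhotometry`, `genEncoder`,
  `genMovie`, `genLinescan`, `genDoseResponse`, `genHypnogram`), plus
  CSV/TIFF/JSON readers and writers and a configurable pipeline driver
  (`runPipeline`; a thin CLI wrapper lives in `inst/scripts/`).

The methods vignette (`vignettes/sensor-pipelines.Rmd`) documents every
model, parameter default and design decision.

## Worked example

Fit a synthetic titration and analyse a synthetic optogenetic trial:

```r
library(SensorPipelines)

dr  <- genDoseResponse(1)                     # EC50 ground truth 75 nM
fit <- fit4PL(dr$doses, dr$responses, weighting = "relative")
fit
#> DoseResponseFit: EC50 = 6.831e-08 mol/L, Hill = 1.07 , top = 0.997 , bottom = 0.00253

tr  <- genPhotometry(1)                       # rise 6.77 s, decay 16.31 s
res <- analyzeStimTrial(tr, traceMetadata(tr)$groundTruth$trains[[1]])
res@peakZ
#> [1] 160.9202
res@riseFit
#> KineticsFit ( rise ): tau = 7.383 s, amplitude = 170.3 , R2 = 1
res@decayFit
#> KineticsFit ( decay ): tau = 17.16 s, amplitude = 170.7 , R2 = 1
```

The fitted EC₅₀ of 68 nM sits within the 10% noise of the 75 nM ground
truth; the trial pipeline recovers the 6.77-s rise and 16.31-s decay
constants within a few percent on this single noisy trial (medians over
seeded replicates land closer still), and the peak z-score is the
maximum of the processed trace during the laser-on period.

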