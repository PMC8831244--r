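Package: SensorPipelines
Title: Analysis Pipelines for Genetically Encoded Neuropeptide Sensor Imaging
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of fluorescence recordings from genetically
    encoded GPCR-based neuropeptide sensors (orexin and related peptide
    indicators). Provides fundamental trace operations (dF/F0 with an
    n-point pre-ligand baseline, binning, Savitzky-Golay smoothing,
    median-anchored linear detrending, baseline z-scoring), one-phase
    exponential association/decay kinetics fitting and four-parameter
    logistic dose-response fitting; trial- and event-locked fiber-photometry
    analysis (optogenetic stimulus trains, behavioural events, sleep-state
    transition amplitudes from hypnograms); rotary-encoder locomotion bout
    detection with bout-aligned fluorescence metrics; high-speed dual-channel
    line-scan activation kinetics with red-dye arrival gating; and a
    two-photon cortical pipeline (field-of-view dF/F0, most-active-minute
    selection, pixelwise binarization, Gaussian smoothing, Richardson-Lucy
    deconvolution, percentile-band circular ROI identification and pairwise
    Pearson correlation analysis). Seeded synthetic-data generators emulate
    every supported input modality with known ground truth so that all
    pipeline stages are testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    matrixStats,
    jsonlite,
    tiff,
    EBImage
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Preprocessing, CellBasedAssays
RoxygenNote: 7.3.3
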