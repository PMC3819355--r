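---
title: "SNR and CNR definitions for fMRI time series: models and methods"
author: "fmricnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNR and CNR definitions for fMRI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmricnr)
```

## The problem

An fMRI time series is modelled as the sum of an activation signal
$S(t)$ — a baseline $b$ plus small task-induced fluctuations — and a
composite noise series $N(t)$ with standard deviation $\sigma_N$.  The
literature quantifies the "signal-to-noise" of such data under at least six
different conventions, which differ in what is placed in the numerator:

| Definition | Formula | Family |
|---|---|---|
| 1 | $\overline{S(t)}/\sigma_N$ | mean-signal (temporal SNR) |
| 2 | $a/\sigma_N$ | amplitude CNR |
| 3 | $20\log_{10}(a/\sigma_N)$ | amplitude CNR, dB |
| 4 | $\sigma_S/\sigma_N$ | fluctuation CNR |
| 5 | $\sigma_S^2/\sigma_N^2$ | fluctuation CNR, variance |
| 6 | $20\log_{10}(\sigma_S/\sigma_N)$ | fluctuation CNR, dB |

Here $a$ is the amplitude of the activation signal (highest peak minus
baseline), and $\sigma_S$ is the standard deviation of the
baseline-subtracted activation course.  Because the same data can yield a
Definition-1 value of 1000 and a Definition-4 value of 0.45, values are not
comparable across conventions; this package computes all six, converts
between them where a closed form exists, and links each to the power of
detecting the activation with a general linear model (GLM).

The identities implemented in `metricSet()`, `toDb()`, `fromDb()` and
`amplitudeFromPsc()` are exact: Definition 5 is the square of Definition 4,
the decibel definitions use the amplitude convention
$20\log_{10}(\cdot)$ (never the power convention $10\log_{10}$ — the
reference grids confirm $4.46 \to 12.98$ dB), and the amplitude implied by
a percent signal change $p$ over baseline $b$ is $a = pb/100$.  There is
no design-free path between the amplitude family and the fluctuation
family: $\sigma_S/a$ depends on the stimulus timing and the haemodynamic
response, which is why `runConvert()` refuses cross-family conversions
without a `DesignSpec` context.

## Design templates and the canonical HRF

Three stimulus templates cover most experiments (`designSpec()`):

* **block** — task and rest epochs of 20 s alternating over 200 s, task
  first;
* **event-related (ER)** — 25 impulse events placed uniformly at random,
  without overlap, on the sampling grid;
* **contrast** — two conditions A and B in the repeating pattern
  A-B-A-B-rest (20 s epochs), so each 100 s sequence of alternation is
  followed by one rest block.

Noise-free activation courses are produced by convolving the 0/1 stimulus
function with a canonical haemodynamic response function and anchoring the
highest peak of the response to $a = pb/100$ (peak anchoring).  For the
contrast design, condition A is anchored to $a$ and condition B to $a/2$
("the effect of condition 1 twice that of condition 2"); the contrast
signal analysed downstream is the pointwise difference of the two
baseline-removed courses, with amplitude defined as its maximum minus its
minimum.

**Choice of HRF.**  "Canonical HRF" is used in the field for two closely
related kernels: the SPM-style difference of gamma densities (peak 6 s,
undershoot 16 s) and the Glover gamma-variate difference (peak 5.4 s,
undershoot 10.8 s, undershoot ratio 0.35).  We use the Glover
parametrisation as default (`hrfParams()`), because with TR = 2 s it
reproduces the package's block-design reference grid to within 0.2 %
(session mean 0.328 intensity units above baseline per 1 % signal change;
$\sigma_S = 0.445$), whereas the SPM parameters give a visibly different
session mean (0.439).  Both shapes are expressible through `HRFParams`.

**Numerical conventions.**  Convolution is carried out directly on the
sampling grid (TR = 2 s by default); an `oversample` argument exposes
finer-grid convolution, which changes $\sigma_S$ by well under 1 % for
these templates.  All standard deviations use the population ($1/n$)
denominator — at $n = 100$ samples the difference from $1/(n-1)$ is 0.5 %,
below every tolerance used.  Zero-amplitude signals yield linear CNR 0 and
a missing value (not $-\infty$) on the dB scale.  Event placement uses a
gap construction that samples uniformly over all non-overlapping
configurations and fails with an informative error when the requested
density is infeasible.

## Detection power

`empiricalPower()` simulates `nReps` series
$y = b + \text{signal} + \varepsilon$ with white Gaussian noise, fits the
correctly specified OLS GLM (intercept plus the unit-amplitude convolved
regressor per condition) and rejects via a two-sided $t$ test at
$\alpha = 0.05$ — the task coefficient for block/ER, the contrast
$\beta_1 - \beta_2$ for the two-condition design.  Defaults follow the
community convention; both $\alpha$ and sidedness are configurable
(`simConfig()`).  Because the model is correctly specified and the noise
white, these powers are *maximal*: autocorrelated or structured noise can
only lower them.  `addNoise(type = "ar1")` is provided to study that
effect.

For ER designs the event placement is redrawn independently for every
replicate by default (`redrawEvents`), so the estimate is power averaged
over random event timings and is stable across seeds; with a seeded design
the placement can be held fixed instead.

`analyticPowerOracle()` gives the closed-form noncentral-$t$ power for the
same design matrix, with noncentrality
$\lambda = c^\top\beta / (\sigma_N \sqrt{c^\top (X^\top X)^{-1} c})$,
averaged over placements for ER designs.  It is used in the test suite as
an independent check of the Monte-Carlo machinery; the two agree within
three binomial standard errors over the whole block grid.  At zero percent
signal change the rejection rate equals $\alpha$ (test size), which the
suite checks against 99 % binomial bounds at 2000 replicates.

`referenceTable()` evaluates the full grid (percent signal change 1/2/5 ×
noise SD 0.1–10) and emits one row per cell with Definitions 1–6 and the
empirical power; within an ER table the metric columns come from a single
seeded placement so that $\sigma_S$ scales exactly with the percent signal
change, while the power column redraws placements.  Each cell draws from a
seed-derived substream, so any cell is reproducible in isolation.  For the
contrast design the metric rows describe the difference signal re-seated
on the common baseline (Definition 1 is a property of the recorded series,
which sits at $b$, not of the baseline-free difference course).

## Relation to published reference grids, and known discrepancies

The test suite compares the computed grids against published reference
values.  The block grid agrees column by column: metrics to within 1 % at
printed precision, power to within binomial error.  Two discrepancies are
deliberate, documented outcomes rather than bugs:

* **ER power.**  Under white noise and a correctly specified GLM, power is
  a fixed function of $\sqrt{n}\,\sigma_S/\sigma_N$; with
  $\sigma_S \approx 0.30$ (the value the printed Definition-4 column
  implies) the mid-grid ER power is $\approx 0.83$, while the published
  column prints 0.64–0.75 at cells with identical noncentrality.  No
  white-noise convention can match both columns: the printed power implies
  an effective $\sigma_S \approx 0.24$, disjoint from the printed
  $\sigma_S$.  Simulation with AR(1) noise ($\rho = 0.2$,
  `addNoise(type = "ar1")`) lowers the ER cell to $\approx 0.69$ while
  leaving the block cells essentially unchanged, suggesting temporally
  autocorrelated noise behind the published ER column; the package keeps
  white noise as the default because that is the stated condition of the
  simulation and the one under which the size and oracle checks are exact.
* **Contrast metrics.**  The published contrast power rows for 1 % and 5 %
  signal change, and the Definition-1 column, are reproduced by the
  A-B-A-B-rest template with condition amplitudes $(a, a/2)$
  (predicted 0.97/0.48/0.16/0.07/0.05 versus printed
  0.96/0.46/0.15/0.07/0.05).  The published Definitions 2–6 for the
  contrast, however, correspond to a difference signal about half the size
  of the one this construction yields (printed amplitude
  $1.056\,a$ versus computed $2.016\,a$), and the published 2 % power row
  violates scale invariance against the 1 % and 5 % rows of the same
  grid.  No single scaling convention reconciles these cells with the
  power columns; the package follows its stated construction and the
  corresponding acceptance check is expected to flag exactly these cells.

A related caveat: "similar SD-based CNR implies similar power" holds
exactly between block and ER designs (identical GLM geometry), but not for
the contrast design, whose $t$ test of a coefficient difference has a
different variance factor per unit of contrast-signal $\sigma_S$.  The
property test is therefore scoped to the single-condition designs.

## Volumes: tSNR maps and ROI-based CNR

For 4D data (`VolumeSeries`, NIfTI-1 via RNifti), `voxelwiseTsnr()`
computes each voxel's temporal mean over temporal SD on the raw,
undetrended series (zero-variance voxels map to `NA`).
`roiActivationEstimate()` averages the voxel series inside and outside a
mask to estimate each region's activation course; its baseline is the
course's temporal mean, and its amplitude the maximum above that baseline.
`roiNoiseIsolate()` subtracts the region course from each voxel to isolate
per-voxel noise, and `regionCnr()` combines the two into per-voxel
Definition-2 or Definition-4 CNR values, summarised as mean/min/max per
region.  Each voxel's $\sigma_N$ comes from its own residual series rather
than a region-pooled value, which is what gives the in-mask CNR values
their spread.

Two estimator properties worth knowing:

* the amplitude estimate takes a maximum over noisy samples and is
  therefore biased upward by roughly
  $1.5\,\sigma_N/\sqrt{n_\text{voxels}}$; with tens of voxels and noise on
  the order of the amplitude this bias is visible, which is why recovery
  checks condition on region size and noise level;
* the region-average course retains noise of SD
  $\sigma_N/\sqrt{n_\text{voxels}}$, so $\sigma_S$ estimates carry a small
  additive variance term, and a mask containing no activation yields a
  Definition-4 CNR near $1/\sqrt{n_\text{voxels}}$ rather than exactly 0.

## The synthetic-volume generator

`synthVolume()` emulates the two real-data scenarios: *resting* mode is
constant baseline 100 plus white Gaussian noise everywhere; *task* mode
adds a planted, HRF-convolved activation course to every voxel of a mask.
It is fully seeded (bitwise reproducible) and is the fixture behind every
volume test: a resting volume at noise SD 8 has a mean tSNR of
$100/8 = 12.5$, and task volumes round-trip their planted psc and noise SD
through the ROI pipeline.  What it deliberately does not emulate — spatial
noise correlations, drift, motion, physiological noise, partial-volume
anatomy — means that passing recovery tests demonstrate the estimators'
correctness, not their robustness on real scanner data.  Default test
geometries (hundreds of voxels, 100–200 time points) keep the whole suite
in the seconds range; parameter-recovery checks use 64-voxel regions and
200 time points, sizes at which the estimator biases above stay below the
15 % recovery tolerance.

## Limitations

* Noise is white (optionally AR(1)) Gaussian; no physiological or
  drift components, no Rician magnitude effects — so all powers are upper
  bounds for real data.
* Power is per time series; no multiple-comparison correction across
  voxels.
* No preprocessing (motion correction, slice timing, detrending) is
  performed or emulated.
* The amplitude of noisy region courses is estimated by a maximum and is
  noise-biased upward; a robust peak estimator is a possible extension.
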