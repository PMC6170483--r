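---
title: "Wavelength selection for PLS calibration of portable vibrational spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection for PLS calibration of portable vibrational spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(specsel)
```

## The problem

Portable near-infrared and Raman spectrometers can estimate the iodine
value (IV, g I₂ per 100 g oil — a measure of lipid unsaturation) of
edible-oil blends directly from a spectrum, replacing wet-chemistry
titration in the field. The calibration is a PLS1 regression of IV on
hundreds or thousands of spectral channels, and its robustness depends
strongly on which channels enter the model: portable instruments carry
detector regions that are essentially baseline noise, and retaining them
inflates prediction error. This package implements the calibration
pipeline — Kennard–Stone partitioning, mean centering, PLS1 with
cross-validated latent-variable choice — together with four
resampling-based wavelength-selection algorithms (MCUVE, CARS, BOSS,
VCPA) and a repeated-evaluation benchmark, driven by a synthetic
oil-blend spectrum generator with a known truth mask so that selection
quality can be scored as recall of genuinely informative channels.

## Model and protocol

PLS1 decomposes the centered calibration spectra as `X = T P' + E` and
the centered response as `y = T q' + f`, with the scores `T` built from
covariance-maximising weights (NIPALS with deflation). The regression
vector `b` in centered space reproduces the score-space predictions
exactly; at the full rank `min(n − 1, p)` (with `p ≤ n`) it coincides
with ordinary least squares, which the test suite uses as an external
oracle.

The evaluation protocol mirrors standard chemometric practice:

* **Partitioning.** Kennard–Stone max–min selection on Euclidean
  distances in raw spectral space; 36 of 59 samples to calibration by
  default. The algorithm is deterministic; all ties break to the lowest
  sample index.
* **Preprocessing.** Mean centering only, with means estimated on the
  calibration rows and applied to the test block. No SNV, MSC or
  derivatives.
* **Model order.** 5-fold cross-validation over 1–10 latent variables;
  folds are a seeded random permutation cut into contiguous near-equal
  blocks, centering is re-estimated inside each training fold, and ties
  in RMSECV resolve to the smallest count.
* **Metrics.** RMSEC/RMSEP with the plain-`n` denominator; `Q²` as one
  minus the normalised squared error. `Q²cv` uses pooled out-of-fold
  predictions — the only reading under which it differs from the
  calibration fit. Robustness across stochastic repeats is the sample
  SD (`n − 1` denominator).

## The four selectors

All four interrogate populations of PLS sub-models rather than a single
fit. Their reference configurations are 500 Monte-Carlo runs (MCUVE),
100 sampling runs (CARS), 1000 bootstrap subsets per iteration (BOSS),
and 50 EDF runs × 1000 binary-matrix sub-models with a 10% best-model
fraction and 14 final candidates (VCPA); every selector re-chooses its
latent-variable count per evaluated subset by 5-fold CV.

**MCUVE** ranks channels by the stability `c = mean(b)/sd(b)` of their
regression coefficients across PLS fits on random 80% subsamples.
Appended artificial noise channels (one per real channel, amplitude
1e-3 of the median channel SD) calibrate the elimination cutoff: a real
channel survives only if `|c|` exceeds the largest artificial `|c|`.
The survivors are ranked by `|c|` and every prefix of the ranking is
scored by cross-validation; the best prefix is returned. The method
combines the artificial-channel cutoff with rank-plus-CV subset sizing;
the stability runs share one latent-variable count (the full-spectrum
CV choice) so all coefficient vectors live in one model space.

**CARS** alternates two pressures over 100 runs: a forced exponential
shrinkage (EDF) of the retained-channel count from `p` down to 2, and a
competitive "survival of the fittest" resampling (ARS) of channels with
probability proportional to their absolute coefficients in a model fit
on a random 80% of samples. The EDF ratio is applied to the original
channel count and capped by the current survivors, with a floor of two
channels (also enforced after the ARS draw); the subset of the
lowest-RMSECV run wins. One shared fold assignment scores all runs, so
comparisons are paired.

**BOSS** generates 1000 bootstrap channel subsets per iteration under
sampling weights that start uniform and accumulate the normalised
absolute coefficient vectors of the best 10% of sub-models (each
scaled to unit L1 mass so every good model contributes equally).
Channels absent from all best models get weight zero and can never
return — soft shrinkage. Iteration stops when the best subset is no
larger than its latent-variable count plus one, when the weight support
stops shrinking for three consecutive iterations, or at a safety cap of
30 iterations; the lowest-RMSECV subset seen anywhere is returned. The
reference description leaves the stopping rule and the normalisation
norm open; both choices here are documented interpretations.

**VCPA** couples binary matrix sampling (every live channel included in
each of 1000 sub-models with probability 0.5, degenerate rows redrawn)
with model population analysis: channels are ranked by how often they
appear in the best 10% of sub-models, and the live set shrinks along a
geometric schedule `n_i = round(p (ω/p)^{(i−1)/(runs−1)})` from `p` to
ω = 14 over 50 runs. The schedule realises the required exponential
shrinkage with the stated endpoint; it is isolated in
`vcpa_edf_counts()` so it can be swapped. The 14 survivors then undergo
an exhaustive search: all 2¹⁴ − 1 subsets are scored by RMSECV under
one shared fold assignment and the minimum is returned, ties resolving
to fewer channels and then lexicographic order.

## What the generator emulates — and what it does not

`generate_dataset()` produces 59-sample blends of four oil components
(soybean, olive, peanut, blend; iodine values 130, 84, 96, 108 so blend
responses land in roughly 86–126). Mixture fractions are Dirichlet(0.5)
draws on the simplex, rejection-clipped to the per-component design
bounds (0–0.8546, 0–0.6934, 0–0.8835, 0–0.8546); the 0.5 concentration
pushes draws toward the simplex boundary the way a deliberately wide
mixing design does. Pure spectra are sums of Gaussian bands at the
characteristic NIR overtone/combination positions (1168, 1210, 1392,
1414, 1660, 1726, 1761 nm, filtered to the instrument axis) or the ten
common oil Raman bands (868–1745 cm⁻¹), with per-component amplitude
patterns that make the fractions spectrally identifiable and
unsaturation-sensitive bands scaling with the component's iodine
value. Three instrument profiles fix the channel axes: 125 channels
over 900–1700 nm, 3108 over 1100–2100 nm, 3122 over 175–3200 cm⁻¹.

The additive baseline is a low-order polynomial with small seeded
coefficients, *shared by all samples* like an instrument background —
so centering removes it exactly and, with both noise SDs at zero, the
data follow the bilinear PLS model exactly: three latent variables
(four simplex-constrained fractions) reproduce the response to
numerical precision. Per-sample multiplicative scatter, wavelength
calibration error, and Lorentzian/Voigt lineshapes are deliberately out
of scope; passing tests therefore say nothing about robustness to
those effects. Default noise: 0.005 absorbance-equivalent per channel
and 0.5 g I₂/100 g on the response (a typical titration
repeatability).

`planted_dataset()` is the scoring fixture: exactly five channels carry
signal, each tracking an *independent* Uniform(0, 1) latent
concentration, and the response is a weighted sum of the five mapped
into the IV range. Independence matters — a first design derived the
five channels from the four simplex fractions, whose three degrees of
freedom make two of the five channels mathematically redundant, so no
parsimonious selector could ever reach recall 0.8. With independent
factors every planted channel is irreplaceable. Uninformative channels
carry structureless baseline variation at one third of the signal SD:
near-zero variance there would inflate the raw regression coefficients
of noise channels (spectra are centered, never variance-scaled, so
coefficient-magnitude-based selectors are scale-sensitive), while
equal variance would let 120 same-scale noise covariances drown the
five signal covariances at 36 calibration samples — a regime in which
stability- and coefficient-based selection genuinely breaks down. One
third is the realistic middle: no-absorption regions wiggle visibly
but well below the analytical bands.

## Numerical choices

* Rank exhaustion: a PLS component whose weight vector has numerically
  zero norm (relative tolerance 1e-12 against the first component)
  stops the fit early; the achieved count is reported and carried
  forward in cross-validation.
* All retention counts use half-away-from-zero rounding; `round()`'s
  half-to-even convention would make schedule endpoints seed-dependent.
* Every stochastic routine takes a `seed` and restores the caller's
  RNG state; `run_benchmark()` derives repeat `r`'s seed as
  `base_seed + r`, and the Kennard–Stone split is computed once since
  it is deterministic. Re-running with the same base seed reproduces
  the report byte for byte.
* Fold assignments are shared (paired) across every subset comparison
  within a selector, removing fold noise from subset rankings.
* Failed repeats inside the benchmark are excluded from means/SDs and
  counted per method, since resampling selectors can degenerate on
  hostile configurations.

## Problem sizes in the tests

The suite validates the selectors at two scales chosen to keep a full
run inside a few minutes of CPU: module tests use 40-sample,
40–50-channel planted fixtures with reduced run counts, and the
end-to-end recovery check uses the reference 59 × 125 fixture with all
selector defaults over 20 seeds. The exhaustive-stage optimality proof
re-enumerates all 16383 candidate subsets once at the reference size.
The benchmark protocol itself (50 repeats) is exercised at 2–3 repeats
in tests; the repeat count only scales the summary, not the code path.

## Known limitations

* PLS1 only — one response at a time; no PLS2, kernel PLS, or
  prediction intervals.
* The CSV dialect is fixed (sample-id column, numeric channel headers,
  trailing response column); instrument-native JCAMP-DX/SPC formats are
  not read.
* The synthetic generator is a test harness, not a claim of spectral
  realism; conclusions about method ranking on real oils require real
  spectra.
* MCUVE's artificial-channel cutoff can be strict on sparse-signal
  data (few survivors); the implementation then still returns the best
  prefix of the survivors rather than widening the cutoff.
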