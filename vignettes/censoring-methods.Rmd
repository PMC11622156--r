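---
title: "Censoring-based comparison of size III and size V visual fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censoring-based comparison of size III and size V visual fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfcensor)
```

## The problem

Static perimetry estimates a contrast-sensitivity threshold, in decibels of
stimulus attenuation, at each of the 52 seeing locations of the 24-2 grid.
With the standard Goldmann size III stimulus, thresholds below roughly
17–25 dB are unrepeatable: in damaged retina the staircase wanders through
a range where the response is dominated by noise, so two same-day tests of
the same eye can disagree by many dB at such points. The larger size V
stimulus keeps a usable signal deeper into damaged field, which is why
practices switch to it in severe loss — at the cost of comparability with
the size III history.

`vfcensor` implements a harmonization with two ingredients:

1. **Censoring.** All raw sensitivities strictly below a stimulus-specific
   threshold `t` are replaced by `t`. This removes the noise-dominated
   range instead of pretending its values are measurements.
2. **Total deviation (TD).** Censored sensitivities are converted to
   age-corrected deviations from a per-stimulus normative surface,
   `TD(p) = max(S(p), t) − N_s(p, age)`, putting both stimuli on a common,
   age- and eccentricity-free scale.

Censoring is applied **before** TD conversion; the censorship flag refers
to the raw sensitivity (strictly below `t`; equality is not censored).
The pointwise difference `d = TD_V − TD_III` over all locations of all
same-day pairs is the basic observable.

## Choosing the thresholds

`fit_censor_thresholds()` evaluates every candidate pair `(t_III, t_V)` on
a grid (default 15–30 dB in 1 dB steps for both stimuli, bracketing the
debated dynamic-range cutoffs with margin) and summarizes `d` over the
*censored* subset — point pairs where at least one stimulus was censored.
The selected pair is the one whose mean censored difference is closest to
zero. Two guards shape the argmin:

* **`min_count`** (default 30): cells whose censored subset is smaller are
  excluded, so the optimum is never estimated from a handful of points.
* **`mean_tol`** (default 0.1 dB): cells whose `|mean|` is within this
  margin of the minimum are treated as tied, and ties are resolved by the
  lowest SD of the censored differences, then the lower `t_III`, then the
  lower `t_V`.

The equivalence margin deserves explanation, because it is the one place
where a naive argmin misbehaves. When a deficit is deep, many locations
fall below both thresholds and censor deterministically — the III value
becomes exactly `t_III`, the V value exactly `t_V` — so their difference
contribution is the constant `(t_V − t_III) − (N_V − N_III)`. Every grid
diagonal with `t_V − t_III` equal to the local normative offset therefore
drives the censored mean to within a few hundredths of a dB of zero, while
exact floating-point ties never occur. A strict argmin then selects
essentially at random along that diagonal; differences of 0.01–0.05 dB in
a mean over thousands of points carry no information about threshold
quality. What does discriminate along the diagonal is the *spread*: at the
true noise floors the censored differences collapse to near-constants,
while thresholds above the floors sweep genuinely measurable (noisy)
points into the censored subset and thresholds below them leave residual
sub-floor noise uncensored. The selection rule — mean closest to zero,
low-SD tie-break within 0.1 dB — encodes exactly that. Setting
`mean_tol = 0` restores the strict argmin for anyone who wants it, and the
`tie_break` field of the fit records which rule decided.

`evaluate_cell()` is a deliberately plain single-cell reference
implementation; the fit's vectorized sweep is tested against it (and
against a second naive full-grid search) for exact agreement.

## The agreement battery

`vf_agreement()` bundles, at a fixed threshold pair:

* mean ± sample SD of `d` for censored pairs, uncensored pairs and all
  pairs, with the censored/uncensored split defined by the OR of the two
  raw-value flags;
* a two-sided one-sample *t*-test of `d` against zero
  (`df = n − 1`; undefined and flagged `NA` under zero variance);
* OLS of `TD_V` on `TD_III` — the axis roles are fixed — reported as
  slope, intercept and `r² = 1 − SSE/SST`, to be read against the line of
  unity `y = x`;
* Bland–Altman per-point means and differences with limits of agreement
  at mean ± 2 SD (the multiplier is an argument; 1.96 is available).

The difference direction is fixed as size V minus size III everywhere.
Point pairs are pooled and treated as independent observations, which is
the convention for pointwise perimetry comparisons but understates
uncertainty when deviations are correlated within a field;
`cluster_bootstrap_diff()` resamples whole field pairs and returns a
percentile interval for the mean difference as a robustness check.

## The normative surrogate

The perimeter vendors' normative databases (size III SITA, size V full
threshold) are proprietary, so the package provides a parametric
hill-of-vision surrogate: expected sensitivity falls linearly with
eccentricity from a foveal peak, ageing is linear per decade, and size V
sits a uniform offset above size III, reflecting its larger spatial
summation. Defaults — peak 34 dB, 0.25 dB/deg, +4 dB offset, −0.7
dB/decade, reference age 45 — are typical textbook magnitudes; they are
*not* claimed to match any vendor database, and every downstream statistic
is invariant to which normative table is plugged in. Measured tables load
from CSV (`read_normative_csv()`), stored in the right-eye frame; left-eye
locations are mirrored in x at lookup. TDs are kept at floating precision
rather than rounded to integer dB, since sub-dB means are the object of
interest.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not perimetry physics. Per participant it draws an age (normal,
truncated to 19–90 years), a tested eye, a peak deficit severity (normal,
truncated to 0–30 dB) and a disease pattern; pairs are assigned to
participants round-robin, so the published repeated-measures ratios
(about 8.8 sessions per glaucoma participant, 1.6 per NAION participant at
the default cohort sizes of 1053/120 and 939/586) fall out of the counts.
Repeat sessions share the participant's true field and differ only in
observation noise — within-subject correlation between sessions beyond the
shared truth is not modelled.

* **Patterns.** NAION: altitudinal loss, one hemifield depressed by the
  severity with a linear transition band (default 6° wide; width 0 gives a
  hard step). Glaucoma: arcuate loss over a Bjerrum annulus (10–21°
  eccentricity) in one hemifield, plus an optional nasal step at half
  depth. The same true deficit underlies both stimuli: the premise of the
  method is that the two stimuli measure one field and differ only through
  normals, floors and noise. Default severities (18 ± 6 dB glaucoma,
  16 ± 6 dB NAION) give the moderate-to-severe regime the method targets,
  with roughly half of NAION locations censored at the default floors.
* **Noise.** Above the stimulus's sensitivity floor, Gaussian test–retest
  noise whose SD interpolates linearly from 1.3 dB (III) / 1.2 dB (V) at
  30 dB to 3.0 / 2.0 dB at the floor — published pointwise inter-test
  variabilities. Below the floor (21 dB for III, 24 dB for V), the default
  `"uniform"` mode draws from the discrete uniform on `{0, …, floor − 1}`:
  the observation carries no information about the true value. This
  sub-floor regime is what makes the floors recoverable by the threshold
  search; the alternative `"clamp"` mode keeps the Gaussian everywhere and
  demonstrates the optimizer's behaviour when no floor exists.
* **Output.** Observations are rounded to integer dB and clamped to
  [0, 50], mirroring perimeter export; everything is a deterministic
  function of the spec's seed.

What the generator does **not** emulate — SITA/full-threshold staircase
dynamics, fixation losses and false responses, media opacity, learning
effects, location-varying normative offsets between the stimuli, and
within-subject session correlation — bounds what passing tests show: they
validate the estimator and its statistics under the stated noise model,
not the clinical thresholds themselves. The published clinical values
(21/24 dB thresholds, censored difference 0.0 ± 1.9 dB, slope 0.92,
r² = 0.70) come from a proprietary dataset and are not reproducible from
code; the package's validation instead checks structural counts, oracle
equivalence, floor recovery, and qualitative mirrors of those results on
simulated cohorts.

## Numerical and edge-case choices

* Strict inequality for censorship (`S < t`); equality is uncensored.
* `censor_threshold = -Inf` disables censoring and yields the plain
  deviation field; thresholds `(0, 0)` behave identically on [0, 50] data.
* Empty censored subsets give `NA` means (flagged, excluded by
  `min_count`); single-point subsets give `NA` SD.
* Sample SDs use denominator `n − 1` throughout.
* The `"<0"` instrument floor token parses to 0 dB — such points are below
  every candidate threshold, so the choice cannot affect any censored
  statistic.
* Blind-spot rows are dropped on read with a logged count; a missing or
  duplicated location is an error naming the field and location.
* Truncated normal draws use rejection sampling, deterministic under the
  spec seed.

## Problem sizes in the validation suite

The test suite exercises full-size cohorts (1992 pairs, 103,584 point
pairs) for counting identities, and 500-pair mixed cohorts (250 glaucoma +
250 NAION at the published session ratios) across five seeds for floor
recovery, censoring-variability and line-of-unity checks; oracle
equivalence uses ≤ 20 pairs on 5 × 5 grids where the naive search is
exact. These sizes give stable statistics (SE of a censored-subset mean
below 0.01 dB) while keeping the suite quick to run.

## Known limitations

* The surrogate's uniform V offset makes the normative difference between
  stimuli eccentricity-free; real databases differ by location, which
  would sharpen the threshold search's mean objective relative to the
  simulated case.
* The pooled *t*-test and OLS inherit the independence convention; use the
  cluster bootstrap when drawing inference about mean offsets.
* Only the 24-2 grid is supported; 30-2/10-2 layouts, kinetic perimetry
  and proprietary export formats are out of scope, as are pattern
  deviation, general-height corrections and probability maps.
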