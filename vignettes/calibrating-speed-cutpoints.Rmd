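---
title: "Calibrating walking-speed cut-points from activity counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating walking-speed cut-points from activity counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedcuts)
```

## The calibration problem

Count-based accelerometers reduce body acceleration to a non-negative
integer per epoch. Interpreting those counts as walking behaviour
requires thresholds: a floor that separates non-ambulation from
walking, and further thresholds that grade walking speed into the bands
used in stroke rehabilitation to distinguish limited (0.41–0.8 m/s)
from unlimited (0.81–1.2 m/s, >1.2 m/s) community ambulation.
`speedcuts` implements the full calibration pipeline — count
digitization, trial segmentation, ROC-based threshold selection — plus
a calibrated synthetic cohort generator so that every stage can be
exercised and tested without access to clinical recordings.

## The count engine and its assumptions

Commercial count algorithms are proprietary; the engine here is an
*open emulation* with the documented structure:

1. zero-phase Butterworth band-pass, 0.25–2.5 Hz by default
   (overall order 4, applied forward–backward);
2. 12-bit digitization over ±6 g, zero acceleration at mid-scale
   level 2048;
3. rectification, saturation at a 2.13 g ceiling, a 0.05 g dead-band
   below which a sample contributes nothing, quantization in steps of
   1/128 g;
4. summation of quantized levels per second, then aggregation to 15 s
   or 60 s epochs (trailing partial epochs dropped);
5. vector magnitude across the three axes.

Bit-exact equivalence with any commercial implementation is explicitly
*not* a contract. What the engine guarantees — and what the tests
assert — are the properties downstream analyses actually rely on:
zero input gives zero counts, sub-dead-band motion gives zero counts,
counts are non-negative integers at every stage, counts are monotone in
the amplitude of in-band motion, and 60 s epochs are exactly the sum of
their four 15 s epochs. The dead-band (0.05 g), ceiling (2.13 g) and
quantum (1/128 g) are tunable arguments of `accel_to_counts()`; their
defaults are plausible magnitudes for a ±6 g 12-bit device, chosen once
and treated as fixed engine constants.

Two documented conventions needed a decision:

* **Vector magnitude.** Descriptions of tri-axial counts sometimes call
  the combined value a "summation" of the three axes, but the
  established convention in the cut-point literature is the Euclidean
  norm rounded to the nearest integer. `vector_magnitude()` defaults to
  Euclidean and offers `method = "sum"` for the literal reading.
* **Low-frequency extension.** The commercial low-frequency filter
  mode is documented only by its purpose (sensitivity to slow,
  low-intensity movement). `filter_spec("lfe")` lowers the low cut
  from 0.25 Hz to 0.05 Hz with the same high cut; the mode's tested
  contract is behavioural — a slow (0.1 Hz) supra-dead-band oscillation
  produces strictly more counts under `lfe` than under `default`.

The engine assumes 30 Hz input; other rates are rejected rather than
resampled, because the passband and per-second accumulation are defined
at that rate.

## Segmentation and category assignment

Each annotated trial is trimmed by 15 s at both ends before epochs are
formed, excluding initialization and termination transients; a trial
must therefore exceed 30 s. One speed is computed per walking trial
(distance / time) and every retained epoch inherits the trial's
category. Boundary semantics follow the published category table:
slow = [0.41, 0.80] m/s with the upper bound inclusive,
medium = (0.80, 1.20] m/s, fast > 1.20 m/s. Walking slower than
0.41 m/s lies outside the scheme and raises a classed error
(`below_minimum_speed`) so that callers exclude such trials explicitly
instead of silently binning them. The three non-ambulation tasks
(sitting, setting the table, washing dishes) are pooled into a single
`nonamb` class, with the task label preserved for provenance.

## ROC calibration

For each of the three category boundaries a binary problem is formed by
**cumulative dichotomization**: everything above the boundary is
positive (non-ambulation vs all walking; non-ambulation + slow vs
medium + fast; all slower vs fast). How the middle boundaries' binary
problems were formed in the original calibration is not documented;
cumulative splits are the default here because the resulting intervals
are contiguous and exhaustive by construction, and
`scheme = "adjacent"` (each pair of neighbouring categories only) is
provided as an alternative.

`roc_curve()` evaluates candidate thresholds at the midpoints between
consecutive distinct scores plus the two infinite endpoints, so the
curve always contains `(sens, 1-spec)` endpoints (0,0) and (1,1) and
one operating point per distinct count. The trapezoidal AUC of this
construction equals the Mann–Whitney pairwise concordance with ties
counted 1/2; the test suite asserts agreement with a brute-force
pairwise oracle to within 1e-9 and cross-checks against an independent
ROC implementation.

The cut-point is the operating point minimizing the corner distance
√((1−Se)² + (1−Sp)²). Numerical choices:

* **Ties** (distances equal within 1e-12) are broken by higher
  sensitivity — favouring detection of walking — then by the lower
  threshold.
* **Integer intervals.** The optimal real threshold `t` (a midpoint
  between observed counts) becomes `T = floor(t)`, so categories occupy
  the contiguous integer ranges ≤T and ≥T+1.
* **Degenerate inputs.** Single-class labels raise
  `degenerate_labels`; a curve with a single operating point raises
  `degenerate_curve`; a stratum missing one of the four categories
  raises `insufficient_classes`.
* **Boundary collisions.** On noisy data an upper boundary can land at
  or below a lower one. The violating boundary is then recomputed with
  its candidate thresholds restricted to values above the lower
  boundary (falling back to `T_lower + 1` if none exists), and the
  event is reported via `message()`.

AUC grading follows the conventional bands (<0.7 poor, 0.7–0.79 fair,
0.8–0.89 good, ≥0.90 excellent, 1 perfect) and is exposed as an
ordered factor so monotonicity is testable.

## The synthetic cohort generator

The generator emulates the *layout* of a calibration study: 42
participants by default, each performing sitting (5 min), setting the
table (3 min), washing dishes (6 min) and two 6-minute walks at a
self-selected and a brisk speed, with sensors at the waist and ankle.
Self-selected speeds are drawn per participant from a normal
distribution (mean 0.85 m/s, SD 0.25) clipped to [0.41, 1.3] m/s, and
brisk speeds add a clipped normal increment (mean +0.35 m/s), which
populates all three walking bands at roughly the proportions seen in
post-stroke cohorts; one speed is assigned per trial, never per epoch.

Counts are generated at two levels:

* **Count level** (default): per-epoch counts are drawn from a
  lognormal distribution with median equal to the configured
  class-conditional median and log-scale SD `dispersion`. The default
  medians reproduce published per-category medians for waist/ankle,
  vertical/vector-magnitude and 15 s/60 s epochs (e.g. waist VM 15 s:
  0 / 519 / 759 / 1147). The vertical and vector-magnitude draws of an
  epoch share one lognormal quantile, so VM never falls below the
  vertical count, and the horizontal axes are back-filled to be
  consistent with the Euclidean convention. Non-ambulation at 15 s
  epochs has median 0 and is modelled as zero-inflated (zero with
  probability 0.6, otherwise lognormal around a small placement- and
  axis-specific tail median), reproducing a zero median with a positive
  upper tail; at 60 s epochs the published non-ambulation medians are
  positive and a plain lognormal is used.
* **Signal level**: gait-like waveforms (two harmonics of a cadence
  linear in speed, amplitude proportional to speed and larger at the
  ankle, lateral sway at half cadence, sensor noise, 1 g gravity
  offset) and low-motion non-ambulation signals are run through the
  full count engine. This path exercises the engine end-to-end — its
  count *scale* is not calibrated to the published medians, but its
  schema and trimming are identical to the count-level path, and its
  median counts increase with simulated speed.

`dispersion = 0.2` (a within-category coefficient of variation of
about 20%) was fixed at design time as a realistic spread for
steady-state walking counts within a speed band: small enough that
adjacent categories with median ratios of 1.4–1.8 overlap only in
their tails, large enough that the overlap is real and per-category
sensitivities stay below 1. All randomness derives from one master
seed via deterministic sub-streams per participant, trial and stratum,
so identical configurations give byte-identical cohorts and partial
regeneration is reproducible.

What the generator does **not** emulate: hemiparetic gait asymmetry,
walking-aid artifacts, device noise spectra, turns on the walking
track, or any correlation structure between epochs within a trial
beyond the shared trial category. Passing tests therefore demonstrate
that the *machinery* is correct and that cut-point recovery behaves
sensibly under controlled class separation — not that the package
reproduces the original cohort's sensitivities or specificities, which
are properties of unavailable clinical data.

## What the tests establish

* Worked-example fidelity: the shipped published tables (waist
  140/572/990, ankle 401/1862/3265 VM counts per 15 s) classify each
  published class-median count into its true category and partition
  the integers exactly as printed.
* Oracle properties: trapezoidal AUC ≡ Mann–Whitney concordance;
  perfect separation yields AUC 1 with the corner operating point; on
  two unit-variance Gaussians centred 2 SD apart the recovered
  threshold converges to the analytic midpoint (tested as a 10-replicate
  mean at n = 10,000 per class, within 2%).
* Parameter recovery: across 20 seeded 42-participant cohorts the
  recovered waist boundaries fall strictly between the adjacent class
  medians (T1 < 519 < T2 < 759 < T3 < 1147), and the ankle placement's
  mean boundary AUC exceeds the waist's in at least 18 of 20 paired
  seeds — the ankle's wider class separation is a structural property
  of its configured medians. The per-seed comparison uses the mean of
  the three boundary AUCs: the non-ambulation boundary is near-perfect
  for both placements, so a per-boundary strict comparison would be
  dominated by ties.

Simulation sizes in the test suite (cohorts of 1–42 participants,
10,000-draw median checks, 100-instance oracle sweeps) were chosen so
the full suite completes in well under a minute of compute while
keeping Monte-Carlo margins comfortable.

## Known limitations

* The count engine is an emulation; absolute count scales from the
  signal-level path are not comparable to commercial devices, and
  cut-points calibrated on signal-level synthetic data are not
  transferable to real recordings.
* Cut-points are epoch-length specific; only the recommended
  15-second published tables are built in, and the package refuses to
  apply a table to a mismatched stratum rather than rescale.
* Thresholds are optimized on pooled epochs without participant-level
  clustering adjustment, mirroring the original procedure.
* Bootstrap intervals in `summarize_counts()` are percentile intervals
  for the median and are labelled as such; they are not a
  reconstruction of any published interval, whose construction is
  undocumented.
* Confidence intervals on AUC, multi-class ROC surfaces and
  machine-learning classifiers are out of scope.
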