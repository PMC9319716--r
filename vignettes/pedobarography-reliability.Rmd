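---
title: "Test-retest reliability of plantar-pressure insole gait variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reliability of plantar-pressure insole gait variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedreli)
```

## The measurement problem

Dynamic pedobarography records the pressure distribution under the foot
throughout the stance phase of gait.  With instrumented insoles it can be
done inside regular footwear, which makes it attractive for children with
cerebral palsy (CP), whose foot deformities (equinus, planovalgus,
equinovarus) alter foot-ground interaction.  Before a between-session
change in any pedobarographic variable can be attributed to an
intervention, the measurement error of the method in this population must
be quantified: that is a test-retest reliability design, two sessions some
days apart, each limb analysed as its own unit.

`pedreli` implements that analysis chain end to end, together with a
synthetic recording generator that stands in for raw insole data (which
for clinical cohorts is typically not shareable), so every stage is
testable against a known ground truth.

## Reliability statistics

For one variable in one region, the input is an $n \times k$ matrix of
limb-session means ($n$ limbs, $k$ sessions; in the default design
$n = 16$, $k = 2$).  A two-way crossed ANOVA without replication
decomposes the total sum of squares into limbs, sessions and error, and
the intraclass correlation for *absolute agreement of the average of $k$
measurements* is

$$ICC = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$

where $MS_R$, $MS_C$ and $MS_E$ are the between-limb, between-session and
error mean squares.  Confidence intervals use the exact F-based
construction for this ICC form (single-measure bounds from F quantiles
with a Satterthwaite-approximated denominator df, stepped up via
Spearman-Brown); `icc_confidence_interval()` reproduces the established
implementation in `pingouin` to numerical precision, which the test suite
verifies on hundreds of random matrices.

Agreement is banded as poor ($ICC < 0.40$), fair ($0.40 \le ICC < 0.60$),
good ($0.60 \le ICC < 0.75$) and excellent ($ICC \ge 0.75$).

Absolute error measures come from the between-session differences
$d_i = x_{i1} - x_{i2}$ (session 1 minus session 2; the orientation is a
package convention, made testable by the antisymmetry of the results
under session swapping):

$$SEM = \frac{SD_{diff}}{\sqrt{2}}, \qquad
  MDC = 1.96 \sqrt{2}\, SEM = 1.96\, SD_{diff}, \qquad
  LOA = \overline{d} \pm 1.96\, SD_{diff}.$$

$SD_{diff}$ uses the sample ($n-1$) denominator.  Percentage forms divide
by the variable's mean, interpreted as the grand mean over both sessions'
limb means (the natural denominator when no baseline session is
privileged): $SEM\% = 100\,SEM/\overline{x}$, $MDC\% = 100\,MDC/\overline{x}$,
banded as excellent ($<10\%$), acceptable ($10$-$30\%$, boundaries
included) and poor ($>30\%$).

`verify_published_table()` checks this arithmetic against a transcription
of a published 24-row reliability table (whole foot plus three zones, six
variables each) for insole gait data in children with CP: recomputing
SEM, MDC and both LOA bounds from the printed mean differences and
$SD_{diff}$ reproduces every printed value within 0.02 (published tables
round intermediates to two decimals).

## From pressure frames to variables

A recording is a sequence of per-cell pressure frames (kPa) on a sensor
grid sampled at 100 Hz.  Processing proceeds in four steps.

**Detection.**  A footprint is a maximal run of frames whose whole-foot
total force stays at or above 10 N for at least 150 ms.  Force conversion
uses $1\,\mathrm{kPa} \times 1\,\mathrm{cm^2} = 0.1\,\mathrm{N}$.

**Cleaning.**  Amiss footprints are removed by three criteria, each
configurable and individually disableable: activation-based contact time
below 450 ms (`too_short`; genuine paediatric stance phases are well
above this, clipped or truncated contacts well below), fewer than 6
distinct loaded sensor rows (`partial_loading`; part of the foot missed
the insole), and a peak force below half of the recording's median step
peak (`low_force`; grazing contacts, turns).  Manual exclusions are
supported (`user_flagged`).  Which criterion fires first for a given bad
step is profile-dependent; the cleaning contract tested against the
generator is the *removal set*, not the reason labels.

**Masking.**  The three-zone mask assigns each cell by the longitudinal
centroid fraction of its row: hindfoot $[0, 0.30)$, midfoot
$[0.30, 0.60)$, forefoot $[0.60, 1.00]$ of insole length.  Half-open
intervals make the zones an exact partition of the whole-foot mask, which
yields machine-precision conservation laws (whole-foot force and
force-time integral are sums over zones; whole-foot peak pressure is the
zone maximum) that the tests assert.  Percentages are applied to the
insole length, not the per-step loaded length, because that is how
insole-software masks operate.

**Variables.**  Per footprint and mask: maximum force (N), peak pressure
(kPa), force-time integral (trapezoidal, N s), pressure-time integral,
contact area, contact time.  Three of these have no universally fixed
definition, so the package states its conventions explicitly:

* *PTI* integrates the regional instantaneous maximum pressure (a common
  vendor convention); an alternative averaging per-cell time integrals
  over ever-active cells is available via `pti_mode = "cell_mean"`.
* *Contact area* is the maximum instantaneous area of cells at or above
  the activation threshold (default 5 kPa), not the cumulative loaded
  union.
* *Contact time* is the time from the first to the last active frame,
  counted as (active frames $- 1$) $\times$ dt.  This matches the
  trapezoidal integrals, so a cell held at 100 kPa for exactly 1 s yields
  simultaneously FTI $= 10$ N s and contact time $= 1000$ ms.

## The synthetic cohort generator

The generator's defaults encode the emulated study design: 8 children,
both limbs recorded (16 analysis units), two sessions, at least 15 valid
steps per limb, 100 Hz sampling, a 20 cm insole modelled as a
16 $\times$ 6 grid of 1 cm$^2$ cells, and a participant mix dominated by
true equinus with one drop-foot and one bilateral apparent-equinus child.
The affected limb walks with its CP pattern, the other limb with the
typical profile.

Each stance phase is rendered as three spatial Gaussian pressure blobs
(hindfoot/midfoot/forefoot centers at 15%, 45% and 80% of insole length)
modulated by raised-cosine temporal envelopes ordered heel-early to
forefoot-late (hindfoot active over stance fractions 0-0.55, midfoot
0.15-0.80, forefoot 0.35-1.00).  Blob amplitudes scale so the regional
peak force equals the profile's regional weight times the peak body force
(default 170 N).  True equinus constrains the hindfoot weight strictly
below the forefoot weight, which propagates to the tested property that
hindfoot peak pressure stays below forefoot peak pressure in every step.
Swing phases carry only a uniform 0-1 kPa sensor-noise floor, below the
5 kPa activation threshold by construction.

Test-retest structure is multiplicative on the log scale: each limb
carries stable trait multipliers (regional weights, overall force, stance
duration; SDs 0.20/0.15/0.06), each session adds a common day effect
(SDs 0.03) plus a limb-session interaction (SDs 0.05/0.04/0.03), and each
step adds small residual jitter (SD 0.02, onset jitter 0.02 of the step
period).  The stance multiplier product is clamped to $[0.85, 1.2]$,
physiological bounds that also keep valid and truncated footprints
separated with margin.  Published reliability tables report only session
means, so the per-step noise magnitude is a free parameter; the default
keeps per-limb standard errors small relative to between-session
variation.  All randomness derives from a single integer seed through
hashed substreams per participant, limb, session and stage, so cohorts
are bit-reproducible and adding a participant does not reshuffle the
others.

Amiss steps are injected by truncating a stance to its first 300 ms,
silencing all but the forefoot rows (centroid fractions $[0.65, 0.95)$),
or scaling a stance to 15% force.  All three remain detectable at the
default detection thresholds but are removed at the default cleaning
criteria, so the injected labels are an exact round-trip ground truth;
the test suite verifies exact recovery of the programmed valid step count
and of the removed set over 100 seeded recordings.

What the generator does **not** emulate: realistic center-of-pressure
trajectories, foot-shape-specific loading, shoe or orthosis interaction,
double-bump vertical force profiles, or inter-variable correlations
beyond those induced by the shared amplitude and timing latents.  Passing
tests therefore demonstrate the correctness of the processing and
statistics on signals with known structure, not clinical validity on real
Pedar data.

## Numerical choices and degenerate inputs

* Integration is trapezoidal with uniform $dt = 1/\mathrm{rate}$.
* Interval boundaries: footprint frame intervals are half-open; band
  boundaries follow the stated inequalities exactly (0.40/0.60/0.75 for
  ICC; 10 and 30 assigned to "acceptable" for MDC%).
* Zero variance anywhere is handled explicitly: a constant matrix raises
  a "degenerate data" error for the ICC point estimate; fully noiseless
  data with real limb variation give $ICC = 1$ with a collapsed $(1, 1)$
  interval; $SD_{diff} = 0$ gives SEM, MDC and LOA all zero.
* For pathological inputs (very small $n$ with vanishing between-limb
  variance) the F-based CI construction can degenerate where the
  Spearman-Brown step-up crosses its pole; bounds are then inverted or
  non-finite and are returned as computed, matching the reference
  implementation rather than silently repairing them.  In the study-like
  regime the interval always brackets the estimate.
* The moment estimator of the ICC is biased downward at small $n$; the
  recovery tests quantify this at $n = 16$, where the bias is negligible
  in the excellent range (population ICC 0.8-0.95) but material at low
  population ICC.  Confidence-interval coverage stays at its nominal
  level throughout, so interval estimates remain trustworthy where the
  point estimate is not.
* Display rounding (2 decimals, round-half-even) and the clamping of
  negative CI lower bounds to 0 apply only to the CSV display surface;
  the JSON companion always carries full precision and unclamped bounds.

## Problem sizes used by the test suite

The packaged checks run the generator at cohort sizes matching the
emulated design (8 participants, 15-18 steps per limb) and Monte-Carlo
studies at 1000 replicates per population ICC level; recordings for
property checks use 2-18 steps.  These sizes were chosen to characterise
the estimators well while keeping the default check fast to run
routinely.

## Known limitations

* Only two-session designs are supported by the Bland-Altman/SEM/MDC
  path ($k = 2$); the ANOVA and ICC accept general $k$.
* The text `.ppr` format assumes uniformly spaced sensor rows; vendor
  formats (Pedar `.sol`/`.asc`) are out of scope.
* No center-of-pressure or gait-line analysis, no automatic left/right
  detection, no 3D pressure-map rendering.
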