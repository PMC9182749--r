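---
title: "Heartbeat-dynamics regimes in running sessions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat-dynamics regimes in running sessions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runregimes)
```

## The problem

A wrist-worn device records three channels during a run — heart rate (bpm),
speed (m/s) and altitude (m) — at irregular intervals of a few seconds.
`runregimes` asks how the heartbeat responds, moment by moment, to the
*external energy demand* of the terrain and pace, and classifies short time
windows of a session into four *heartbeat-dynamics regimes* according to the
sign pair (sign ΔE, sign ΔHR): demand and heart rate rising together
(`+/+`), falling together (`-/-`), heart rate rising while demand falls
(`-/+`), and heart rate falling while demand rises (`+/-`).  The `-/+`
fraction of a session is the readout of interest for cardiorespiratory
fitness (VO2max), while determinism from recurrence quantification analysis
(RQA) of the heart-rate signal tracks the emergence of neuromuscular
fatigue across a session.

## The pipeline

### Cleaning

Analysis is restricted to the *intense zone*: samples with HR at or above
90% of the age-predicted maximum `HRmax = 208 − 0.7·age` (Tanaka formula).
Only contiguous zone segments at least one analysis window long are kept,
and every window must lie entirely inside one segment, so windows never mix
in-zone and out-of-zone dynamics.

Sensor despiking removes samples whose global z-score exceeds 3 and
replaces them by linear interpolation from neighbouring inliers.  Despiking
runs on the *raw* channel before grid alignment: interpolating first would
smear a one-sample spike over several grid points and leave sub-threshold
residues that contaminate every overlapping window (skewness is extremely
spike-sensitive).

GPS speed — the noisiest channel — is smoothed with a zero-phase (forward–
backward) Butterworth low-pass filter, cutoff 0.01 in normalized frequency
(fraction of Nyquist; 0.005 Hz on the 1 Hz grid) and order 2.  Zero-phase
filtering is chosen so speed features are not time-shifted relative to
heart rate; deviations from the series mean are filtered and odd-reflection
padding of about `3/cutoff` samples suppresses the startup transient, so
the DC gain is exactly 1.  Altitude is rebased by subtracting its starting
value, making sessions run at different elevations comparable.

All channels are then aligned by linear interpolation onto a common 1 s
grid (the reference device rate), never extrapolating beyond the observed
range; sampling gaps longer than 30 s are treated as segment boundaries
rather than interpolated.

### Window width from the ACF cutoff

The analysis window width is the lag beyond which heart-rate samples stop
being autocorrelated.  Per session, the HR series is detrended (order-1
polynomial by default, escalating once to order 2 if the augmented
Dickey–Fuller gate still rejects stationarity), its sample ACF is computed
with Bartlett large-lag confidence bounds at α = 0.05, and the cutoff lag
`t_cut` is the first crossing of the ACF below the upper bound, linearly
interpolated between the bracketing integer lags.  Widths are aggregated
over sessions as mean ± SD; the chosen width defaults to the conventional
90 s whenever 90 s lies within one SD of the mean, and otherwise rounds the
mean to the nearest 10 s.  An explicit override is available.

No installed R package provides the Dickey–Fuller test, so the package
implements the standard augmented regression (constant, no trend — the
series is already detrended) with `trunc((n−1)^(1/3))` lagged differences
and interpolates p-values from the classical constant-case percentile
table, clamped to [0.01, 0.99].

### Features

The external energy demand proxy sums a potential term `V = g·(z − z0)` and
a kinetic term `K = v²/2`, each min–max normalized to [0, 1] *per session*
(not per window), so `E ∈ [0, 2]` and both terms carry comparable weight
regardless of units or body mass.  `g = 9.80665 m/s²`.  A constant term
(e.g. a treadmill at fixed altitude) normalizes to zero with a warning.

For every 90-sample window (half-open `[start, start + width)`, sliding
point by point on the 1 Hz grid):

* `γ0 = (mean − first value) / σ` — the standardized level shift;
* `γ1 = mean(((x − mean)/σ)³)` — the Fisher–Pearson skewness;
* `ΔX = γ0(X) + γ1(X)` for `X ∈ {E, HR}`.

σ is the *population* SD of the window, for internal consistency with the
skewness definition; the `1/n` factor in `γ1` keeps windows comparable
across lengths and sampling rates.  Both features are invariant under
positive affine rescaling of the channel and flip sign under negation,
which the test suite asserts property-style.

### Clustering

Features are rescaled per axis by `(x − mean)/(α·s)` with α = 3; for
near-Gaussian features this maps >99% of windows into the unit square, and
when coverage falls short α is raised by direct calculation from the
empirical quantiles (heavy-tailed feature distributions).  k-means
(Lloyd/Forgy, L2 objective, tolerance 1e−5 on the centroid shift, stop on
no reassignment) with k-means++ seeding runs with 10 restarts — the
restarts are a package choice; the seeding scheme needs them to be useful —
and an emptied cluster is re-seeded at the point farthest from its former
centroid.  The number of clusters is fixed at k = 4 by default (the four
regimes are the scientific object); a silhouette sweep over k = 2…10 is
available, choosing the k with the largest mean silhouette `s_i = (b_i −
a_i)/max(a_i, b_i)` (singleton clusters score 0; the denominator is the
standard max, consistent with the score's [−1, 1] range).  A best score
below 0.5 triggers a "weak structure" warning: structureless uniform data
plateaus near 0.43 for spurious splits, while genuinely clustered data
(planted blobs ≈ 0.93; the motivating real-data value 0.54) clears it.
Centroids are mapped back to raw feature units and labelled
`sign(ΔE)/sign(ΔHR)`; an exact zero counts as `+` with a warning, and at
k = 4 the four sign pairs must be distinct.

### Session and cohort statistics

Regime frequencies are computed over *all* overlapping windows (the
session maps); hypothesis tests use the greedy non-overlapping subset
(stride = width) so observations are independent.  The temporal analysis
splits normalized session time into thirds (start/middle/end), assigning
each window to the section containing its midpoint.  Across sessions,
Pearson correlations relate per-regime frequencies to device-reported
VO2max (≥3 sessions with VO2max required).  Group differences use a
Shapiro–Wilk normality gate at 0.05: ANOVA with pairwise t-tests when all
groups pass, Kruskal–Wallis with pairwise Mann–Whitney–Wilcoxon otherwise,
always with Bonferroni-adjusted post-hoc p-values; repeated-measures
designs block on the subject (session) factor and use paired post-hoc
tests.

### RQA

Heart-rate regularity is quantified on the intense-zone series with
time-delay embedding (dimension 7, lag 1), a Euclidean recurrence matrix
with radius 5 — interpreted as an absolute distance in bpm-scaled embedded
space, with a percent-of-maximum-distance mode available since the RQA
literature uses both — and determinism
`DET = Σ_{l≥4} l·P(l) / Σ_{l≥1} l·P(l)` over diagonal line lengths outside
a Theiler window of 1 (only the line of identity is excluded; the matrix
diagonal band is stored but not counted).  `0/0` is reported as `DET = 0`
with a flag.  Matrices are kept dense up to 5000 embedded points and only
the statistics beyond that.  Section-wise DET across thirds is the fatigue
readout: rising regularity yields rising DET.

## The synthetic-session generator

There is no deposited data, so the generator is the test substrate.  A
plan places contiguous *regime segments* (default 240 s) whose energy and
heart-rate slopes realize the planted sign pair; defaults emulate an
hour-long intense city run: HR baseline 166 bpm for a 57-year-old (the
deterministic HR then never leaves the 90%-HRmax zone given the bounded
ramps), slope magnitudes 0.04 bpm/s (HR) and 0.2 J/kg/s (energy proxy,
97% realized through altitude, 3% through speed so speed stays positive),
AR(1) heart-rate noise with 85 s correlation time and 1.2 bpm marginal SD,
GPS speed noise 0.15 m/s, altitude noise 0.3 m, sensor spikes of 5–10 SD
at rate 0.002 per sample, and non-uniform sampling intervals of
(5.1 ± 2.6) s for HR, (2.6 ± 1.4) s for speed, (2.0 ± 1.8) s for altitude
— censored below at 0.5 s with the underlying Gaussian moment-matched so
the realized interval mean/SD agree with those targets.  The HR slope was
fixed by a design simulation of the window sign statistic under the AR(1)
noise: slope × width = 3 noise SD recovers the planted sign in ≈99% of
windows.

Three constructions matter for fidelity and were adopted after their
absence proved to corrupt planted ground truth:

* **Continuity.**  Channel ramps integrate across segment boundaries with
  no resets; a per-channel balance scales the *up* slopes when down-time
  dominates (never the down slopes — heart rate faces a one-sided zone
  floor and kinetic energy must stay positive; upward drift is harmless).
* **Bounded, single-flip ordering.**  Segments are ordered greedily to
  bound running excursions and to avoid adjacent segments that flip both
  signs at once, so windows straddling a boundary remain attributable to
  one of the two adjacent regimes instead of scattering across all four.
* **Exact shares.**  Cohort sessions realize planted regime *time shares*
  exactly through per-regime segment durations, instead of quantizing to
  integer counts of equal segments.

`generate_cohort()` plants a rising `-/+` share (0.16 → 0.32) and a
falling `-/-` share (0.29 → 0.19) against VO2max rising 32 → 38 mL/kg/min,
the remainder split evenly; `generate_fatigue_series()` raises the share
of variance carried by a 25 s oscillation linearly with normalized time
(total SD held constant) so DET rises across thirds.  The oscillation
phase is randomized per seed and the period divides the section length —
otherwise fixed partial cycles at the section edges bias section DET
identically in every realization, which a sign test then mistakes for a
trend.

What the generator does **not** emulate: biomechanics or energetics beyond
the sign structure (no gait, grade–speed coupling, or cardiovascular
drift), GPS trace geometry, heart-rate kinetics (lagged first-order
response to load), or between-subject variability.  Ground-truth windows
are those lying fully inside one segment; windows straddling a boundary
have genuinely mixed dynamics and are excluded from recovery scoring while
still counting toward frequencies, as they would in real data.  Passing
tests therefore demonstrate that the pipeline recovers planted sign
structure under realistic noise and sampling — not that four regimes exist
in any particular runner's data.

## Numerical choices and degenerate inputs

* Ties in silhouette-based k selection go to the smallest k; an exactly
  zero centroid coordinate labels as `+` with a warning.
* Constant series: z-score despiking and feature statistics return the
  input/0 (flagged) rather than dividing by zero; the Dickey–Fuller gate
  reports a constant series as stationary with statistic −∞.
* `estimate_window_width()` errors if the ACF never crosses its bound
  within `max_lag_s` (advising a larger lag window) and excludes — with a
  warning — sessions that fail the stationarity gate after both detrending
  orders.
* Serialization uses `%.17g`, so session CSVs round-trip bit-exactly and
  identical sessions produce byte-identical files.

## Problem sizes

The test suite and the acceptance script run on synthetic sessions of
20–60 minutes at 1 Hz: one hour (≈3500 windows) for end-to-end recovery,
16 one-hour sessions for window-width estimation, a 12-session cohort for
the VO2max correlations, and 2 × 50 ten-minute series for the fatigue
analysis — sizes at which every result stabilizes while the whole suite
completes in about a minute.

## Known limitations

* The α-rescaling assumes both feature axes have nonzero variance; a
  session spent at perfectly constant effort fails with an explicit error.
* The ADF p-value table interpolation saturates at [0.01, 0.99], as is
  conventional; extremely strong rejections are reported at the clamp.
* DET is not provably monotone in the recurrence radius (new short lines
  can enter the denominator); the package documents this as an empirical
  regularity, and the tests allow small dips.
* Repeated-measures tests assume a complete, balanced subject × section
  layout.
```{r session-info, echo = FALSE}
sessionInfo()
```
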