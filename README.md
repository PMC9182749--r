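# runregimes

Classify the heartbeat dynamics of running sessions recorded by wearable
devices, and relate them to cardiorespiratory fitness and fatigue.

A wrist device records heart rate (bpm), speed (m/s) and altitude (m) at
irregular intervals of a few seconds.  `runregimes` cleans these channels,
derives an analysis window width from the heart-rate autocorrelation
cutoff, computes two trend features per sliding window — for the heart
rate and for an external energy-demand proxy
`E = V̂ + K̂` with `V = g(z − z₀)`, `K = v²/2`, each min–max normalized to
[0, 1] per session — and clusters the windows in the (ΔE, ΔHR) plane with
k-means++ into four sign-labelled regimes:

```
ΔX = γ0(X) + γ1(X),   γ0 = (x̄ − x₀)/σ,   γ1 = skewness   (X ∈ {E, HR})
```

The sign pair `sign(ΔE)/sign(ΔHR)` names each cluster: `+/+` and `-/-`
are the ordinary proportional responses, `-/+` (heart rate rising while
demand falls) tracks VO2max, and `+/-` is associated with delayed response
and fatigue.  The package also quantifies heart-rate regularity via
recurrence quantification analysis — recurrence rate and determinism
(DET), the fraction of recurrence points on diagonal lines of length ≥ 4 —
whose rise across a session is the fatigue readout.

The analysis domain is the maximal-effort zone: samples above 90% of the
Tanaka age-predicted maximum heart rate, `HRmax = 208 − 0.7·age`.

Because the motivating data are single-subject and not deposited, the
package ships a synthetic-session generator (`synthetic_plan()`,
`generate_session()`, `generate_cohort()`, `generate_fatigue_series()`)
that plants regime segments, wearable sampling-interval statistics, AR(1)
heart-rate noise, sensor spikes and GPS noise, with exact ground truth for
end-to-end validation.

## Worked example

Simulate an hour-long intense run with planted regimes and analyze it:

```r
library(runregimes)

plan <- synthetic_plan(seed = 42)     # 15 x 240 s segments, 1 h session
gs   <- generate_session(plan)
res  <- run_single_session(gs$session)
res
#> <session_result 'synthetic': ok>
#>   3509 windows of 90 s; regime frequencies:
#> freq_pp freq_pm freq_mp freq_mm
#>   0.275   0.213   0.245   0.267
```

3509 overlapping 90 s windows survived the intense-zone restriction; about
a quarter of the session sits in each regime, matching the balanced plan.
The fitted model and section-wise RQA:

```r
res$model
#> <cluster_model: k = 4, n = 3509, objective = 52.9051, mean silhouette = 0.744>
#>   sign labels: -/+ +/+ +/- -/-
res$rqa_sections
#>   section n_embedded        rr       det
#> 1   start       1193 0.2002143 0.9985038
#> 2  middle       1194 0.1766797 0.9986331
#> 3     end       1193 0.1804064 0.9985968
```

The four clusters separate cleanly (mean silhouette 0.744) and carry
distinct sign labels; DET is flat across thirds, as it should be for a
plan without a fatigue trend.  Checking recovered labels against the
planted ground truth:

```r
truth <- ground_truth_labels(plan, width_s = res$width_s)
m <- merge(res$window_labels, truth, by = "window_start_s")
mean(m$label == m$regime)
#> [1] 0.9899244
```

99% of the windows that lie fully inside one planted segment are assigned
their true regime.  `run_cohort()` stacks per-session frequencies across a
directory (or list) of sessions and correlates them with VO2max;
`estimate_window_width()` reproduces the ACF-cutoff window selection from
a set of sessions.

A thin command-line wrapper with `simulate`, `analyze` and `cohort`
subcommands is installed under `inst/cli/runregimes.R`.

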