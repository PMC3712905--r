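---
title: "larvatrax: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{larvatrax: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrax)
```

larvatrax quantifies spontaneous and evoked motor behavior of zebrafish
embryos and larvae recorded one animal per circular well. Because raw video
is bulky and rarely shareable, the package pairs every analysis step with a
seeded synthetic generator that carries its own ground truth, so the whole
pipeline — simulation, rendering, tracking, segmentation, distribution
fitting, thigmotaxis scoring, group statistics — can be validated end to
end without any external data.

## Arena geometry

All spatial analyses are defined on a circular well (default radius
7.5 mm). The inner/outer zone boundary is at 4.5 mm, so the inner zone
holds (4.5/7.5)² = 36% of the area and a spatially uniform animal spends
64% of its time in the outer zone — the chance level against which
thigmotaxis (wall preference) is read.

```{r arena}
arena_geometry()
```

Two thinner bands matter for wall-stay analysis: an animal *reaches* the
wall when it comes within `edge_reach` (0.5 mm) of it, and is considered
*staying* at the wall while within `edge_stay` (1 mm). Reaching starts a
stay event; leaving the stay band ends it. The split avoids flickering
events from an animal hovering exactly at one threshold.

## Synthetic swimming: burst-and-glide

Larval zebrafish swim in discrete bouts separated by rests. The generator
draws alternating bout and rest durations from discrete truncated power
laws Y = aX⁻ᵏ on integer frame support {1, …, duration × frame_rate},
sampled by inverse CDF. Positions advance as a persistent random walk:
during a bout the heading mixes its previous value with a random turn
(`heading_persistence`), speed is lognormal around `mean_speed`, and the
heading is carried across rests with a Gaussian kick per bout
(`bout_turn_sd`). The wall is a hard specular reflector; positions never
leave the well.

Wall preference is generated, not scripted: inside a 1 mm band the heading
is pulled toward the wall tangent tilted outward by `wall_tilt`, with
per-frame weight `wall_affinity / (1 + wall_affinity)`. Affinity 0 gives
area-uniform occupancy (a property the test suite checks with a χ²
test); large affinity gives wall-following.

```{r swim, eval = FALSE}
p <- swim_params(duration = 300, k_rest = 2.5, k_bout = 1.92,
                 mean_speed = 18.9, wall_affinity = 3, seed = 1)
tr <- generate_trajectory(p, arena_geometry())
attr(tr, "activity_true_pct")   # ground truth carried on the object
```

Two deliberate simplifications: rests are perfectly stationary by default
(an optional jitter parameter stress-tests the activity threshold), and
`max_interval` can truncate the duration support — without a cap, the mean
of a k ≈ 2 power law is carried by intervals too rare to appear in one
recording, so realized activity systematically undershoots
`expected_activity()`.

## Rendering and tracking

`render_frames()` turns a trajectory into grayscale frames: a dark
Gaussian blob on a light background, optional pixel noise, written and
read as PNG stacks with a JSON sidecar (`frame_rate_hz`, `mm_per_px`,
well center/radius in pixels). `track()` recovers positions by median-
stack background estimation, thresholding at `threshold_sd` robust
standard deviations, largest-connected-component selection and intensity-
weighted centroiding. Gaps up to `max_gap_fill` frames are linearly
interpolated and flagged `interpolated`; longer gaps are `missing`; a
recording with more than half its frames undetected is an error, not a
silent result. On noiseless synthetic frames the round-trip position error
is well under half a pixel.

## Bout segmentation and power-law fitting

`segment_activity()` thresholds per-frame displacement (default
`movement_threshold` in mm), then applies two cleanups: active runs
shorter than `min_bout` frames are reclassified as rest, and rest gaps of
at most `merge_gap` frames between bouts are merged. The first frame
inherits the second frame's displacement.

Defaults (`min_bout = 2`, `merge_gap = 2`) are meant for noisy tracked
video, where one-frame jitter would otherwise masquerade as micro-bouts.
For clean synthetic trajectories use `min_bout = 1, merge_gap = 0`:
the generator emits genuine one-frame intervals (the mode of a power law
on frame support), and the noise-robust defaults would systematically
merge them, biasing both activity and the fitted exponents.

`fit_power_law()` offers a discrete truncated maximum-likelihood estimator
(recommended; optimizes the exact discrete truncated likelihood) and a
count-weighted log-log least-squares regression on the duration histogram
(the convention of much of the older literature). On 10⁵ samples the MLE
recovers k within ±0.05.

## Thigmotaxis

Beyond zone occupancy, the package scores *how animals leave the wall*:

- `wall_arrival_events()` finds reach-band entries; events still at the
  wall when the recording ends are right-censored.
- `wall_stay_curve()` pools events into P(still at wall at t) over a 30 s
  window. `"continuous"` mode requires uninterrupted residence (censored
  events drop out of the denominator once unresolved); `"instantaneous"`
  mode asks only for presence at t, allowing brief excursions.
- `compare_stay_curves()` tests groups per timepoint with a two-proportion
  test.
- `center_to_wall_paths()` measures the swim path length from leaving the
  central disc (5% of well area) to reaching the wall; path ≥ straight-line
  distance always, and the ratio indexes how directed the approach is.

## Embryo motor analysis

`generate_coiling_series()` draws Poisson coiling events with optional
extra contractions; `summarize_coiling()` recovers rates and grouping.
`generate_curvature_trace()` emits half-sine C-bend pulses in Gaussian
noise. `measure_cbend()` detects excursions crossing
`deviation_threshold`, but backtracks the onset to where the trace last
sat inside `return_tolerance` — the threshold crossing alone would clip
a duration proportional to asin(threshold/amplitude) off both edges. With
an odd `smooth_window` moving average, thresholds of a few smoothed-noise
sigmas, and medians over a handful of replicate pulses, durations are
recovered within one 10 ms frame at noise_sd equal to 10% of the pulse
amplitude.

## Group statistics

`ks_two_sample()` implements the two-sample Kolmogorov–Smirnov test from
its ECDF definition with the standard asymptotic p-value (exact
computation available behind a flag for very small n). The asymptotic form
is conservative at cohort sizes around n = 20 (measured type-I error
≈ 0.03 at α = 0.05). `compare_cohorts()` assembles per-metric group
comparisons into a JSON/CSV report with box summaries (linear-interpolation
quantiles) and significance markers; no multiple-testing correction is
applied, but the number of tests is reported.

## Cohort presets

`cohort_presets()` encodes two contrasting parameter sets, `wt`
(wild-type-like: high activity, fast bouts, strong wall affinity, steep
rest-duration law) and `mutant` (hypoactive, slow, wall-indifferent,
heavy-tailed rests). `simulate_cohort()` adds per-larva heterogeneity:
wall affinities follow stratified lognormal quantiles, so every simulated
cohort has the same composition from weak to strong wall-followers.
Stratification matters twice over. Random draws would let a single extreme
animal dominate the pooled stay curve, making cohort-level results wildly
seed-dependent; and a *mixture* of affinities is what produces the
decreasing-hazard pooled stay curve of real wild-type cohorts — no
single-affinity cohort shows it. The mutant preset also caps rest
durations (`max_interval = 8` s) because rare multi-minute stationary
spells at the wall would read as wall preference.

With these presets, n = 20 per group and 10 min recordings, all the
qualitative group contrasts are significant by KS test, and the pooled
stay curves cross: mutants are *more* likely than wild types to still be
at the wall 1–2 s after arriving (they linger passively), but far less
likely after 10–30 s (they do not actively follow the wall).

```{r presets, eval = FALSE}
a <- arena_geometry()
pr <- cohort_presets(duration = 600)
wt <- simulate_cohort(pr$wt, 20, a, seed = 1)
mu <- simulate_cohort(pr$mutant, 20, a, seed = 2)
compare_cohorts(list(wt = analyze_kinematics(wt, min_bout = 1, merge_gap = 0),
                     mut = analyze_kinematics(mu, min_bout = 1, merge_gap = 0)),
                metrics = c("activity_pct", "mean_bout_velocity_mms",
                            "k_rest", "k_bout"))
```

## Problem sizes and cost

Typical scales: 10-minute recordings at 30 Hz are 18,000 frames per
animal; generating one takes well under a second, and a 20-animal cohort
with full kinematic and thigmotaxis analysis runs in tens of seconds.
Rendering and tracking are the expensive steps (≈1 ms per 96×96 frame
each) and are meant for validation-sized recordings (≤ a few minutes),
not for re-rendering whole cohorts. Power-law fitting is effectively
instant up to 10⁶ samples.
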