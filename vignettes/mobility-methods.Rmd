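---
title: "Methods: multi-sensor mobility analysis with mobilitykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor mobility analysis with mobilitykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilitykit)
```

## Scope

`mobilitykit` implements the analysis chain used to validate consumer GPS
smartwatches and research accelerometers as instruments for monitoring
real-life mobility in older adults. Three measurement streams are supported:
GPS trajectories (a reference logger and a watch), raw tri-axial wrist
accelerometry, and a thigh-worn accelerometer for posture. Because no
participant data ship with the package, a synthetic cohort generator with a
full ground-truth channel stands in for field recordings; every pipeline
stage is exercised and judged against that planted truth.

## GPS pipeline

### Cleaning

Fixes implying a speed above 160 km/h are discarded — the speed a fix is
judged by is the logged speed when the device provides one, otherwise the
haversine distance to the *previous retained* fix divided by the elapsed
time. Judging against the previous retained fix (rather than the immediate
predecessor) prevents one displaced fix from also knocking out its
successor. The threshold reflects the fastest plausible road travel in a
regional deployment; it is a parameter (`trip_params(max_speed_kmh = )`).

### Stop/trip segmentation

Segmentation follows the greedy stay-point approach used in GPS mobility
research. A candidate stop grows from an anchor fix while **every** member
fix lies within 75 m of the running median position of the members; the
median (not the mean) anchors the stop so that a few displaced fixes cannot
drag the center. A candidate becomes a stop when it spans at least 5 min. A
gap of more than 60 min between consecutive fixes terminates the candidate,
so a dwell interrupted by a long signal loss is reported as two stops —
we cannot know what happened in between. Runs of fixes between stops become
trips (moves) when they last over 3 min and their farthest two fixes are at
least 100 m apart; sub-threshold runs are merged into the flanking stops.
Ties resolve toward stops (stop-greedy), consistent with detectors of this
family, and the merge guarantees that stop and move labels alternate within
contiguous data.

The scan is exact but quadratic in the length of a dwell, so the inner loop
is implemented in C++ (`src/staypoint.cpp`); a plain-R reference
implementation in the test suite checks the compiled scan point for point.
Internally the scan works in a local equirectangular plane: the per-axis
median commutes with that projection and planar distances at dwell scale
(&le; 150 m) agree with great-circle distances to well below GPS noise.

### Trips and travel mode

Each move segment becomes a trip carrying its duration and the 90th
percentile of its point speeds. Trips with a percentile speed of at least
25 km/h are *passive* (motorized), all others *active*; the boundary is
sharp (25.0 is passive). Daily trip frequency is the trip count and daily
trip duration the sum of trip minutes. Because diaries and wear schedules
are date-keyed, a "day" is a local calendar date, and a trip crossing
midnight belongs to its start date.

### Life-space metrics

Fixes are projected onto an azimuthal-equidistant plane centered at the
participant's home, which preserves the distance and bearing of every point
to the home exactly; distances between projected points are approximate but
the error is below 0.5% at city scale. Three summaries are computed:

* **Farthest distance from home** — the maximum planar distance, meters.
* **Minimum convex hull (MCH)** — area (m²) and perimeter (m) of the convex
  polygon containing all fixes, via the standard hull construction plus the
  shoelace formula. Collinear point clouds get zero area and the
  farthest-pair segment length as perimeter (the continuous limit of a
  flattened polygon) and are flagged degenerate; the sliver guard treats a
  hull whose area is below 1e-9 of its squared diameter as collinear, which
  is far below any genuine daily footprint.
* **Standard deviational ellipse (SDE)** — the 1-SD ellipse of the point
  cloud from the eigendecomposition of the coordinate covariance with the
  *n* denominator (the GIS convention); orientation is reported as the
  major-axis angle counterclockwise from east in [0, &pi;).

Device comparisons first trim both tracks to the intersection of their
covered time ranges; days with under 8 h of joint coverage are excluded, the
customary minimum GPS wear-time threshold in this literature.

## Accelerometer pipeline

### Activity counts

Raw acceleration is converted to classic actigraphy counts: streams not at
30 Hz are linearly resampled to 30 Hz; each axis is band-pass filtered in
the 0.25-2.5 Hz body-movement band (3rd-order Butterworth, applied
forward-backward for zero phase), decimated to 10 Hz, clipped at the 2.13 g
saturation of the original hardware, rectified, thresholded at the 0.068 g
dead-band, quantized at 0.0164 g per unit (8-bit resolution), and summed
into 60 s epochs. The band-pass removes the static gravity component, so
counts are invariant to device orientation and to any DC offset; the
dead-band makes a motionless device produce exactly zero counts, which the
wear-time rule below relies on. The per-epoch vector magnitude (VM) is the
Euclidean norm of the three axis counts.

### Wear time and intensity

Non-wear follows the 90/2/30 rule on VM counts: at least 90 consecutive
minutes of zero counts, tolerating interruptions of at most 2 min of
nonzero counts when at least 30 min of consecutive zeros flank the
interruption on both sides. Whether the rule is applied to VM or a single
axis is a genuine free choice in the literature; VM is the default here and
the function accepts any counts series. A day is valid with at least 8 h of
wear. The test suite checks the implementation epoch-for-epoch against an
independent window-matching oracle on randomized days.

Epochs are *sedentary* when VM is strictly below 2,860 counts/min — the
wrist cut-point with light and moderate/vigorous classes collapsed into a
single non-sedentary class — so 2,859 is sedentary and 2,860 is not.
Intensity is only defined on wear epochs, and sedentary plus non-sedentary
minutes equal wear minutes by construction. Partial trailing epochs are
dropped from summaries, since the 60 s epoch is the unit of analysis.

### Posture

Thigh-worn streams are classified into sitting/lying vs standing in the
inclinometer style: a 0.5 Hz zero-phase low-pass isolates gravity, thigh
inclination is the angle between the longitudinal axis and vertical
(folded, so the device may be worn either way up), and low-movement epochs
are standing when the mean inclination is under 45° and sitting/lying
otherwise. High-movement epochs (VM at or above the movement threshold,
default 100 counts) are stepping and inherit the standing class. The 45°
default and the movement threshold are configurable because the commercial
algorithm's constants are not published; the package's accuracy claims rest
on synthetic-truth recovery, not on constant matching. When task windows
are scored, the first and last 45 s of each window are discarded to remove
posture transitions; of a 5-min task this leaves exactly three full epochs.

### Steps

Steps are counted from the band-passed (0.5-4 Hz) dynamic vector magnitude
as local maxima above an adaptive threshold — a fixed fraction of the
window's 95th-percentile amplitude, so rescaling the signal does not change
the count — with a 0.3 s minimum inter-step interval. A low absolute floor
rejects windows with no gait energy. Step evaluation is restricted to
declared walk-task windows, mirroring protocols in which participants
self-count 50-100 steps.

## Agreement statistics

For paired device measurements the package reports: Bland-Altman bias
(mean difference) with 95% limits of agreement at bias ± 1.96 SD of the
differences; Spearman's rho (average ranks on ties); percent agreement as
the mean per-pair ratio (test/reference) × 100; and a paired difference
test. Because the raw ratio exceeds 100 when the test device over-reports,
a symmetrized version — 100 − |ratio − 100| per pair, averaged — is always
reported alongside it; the raw mean would hide compensating over- and
under-estimation. The paired test is a t-test when a Shapiro-Wilk check on
the differences does not reject normality at α = 0.05 and the Wilcoxon
signed-rank test otherwise; the gate is automated since manual normality
judgments are not reproducible. All-zero differences are reported as "no
difference" rather than an error.

## The synthetic cohort

The generator plants, per participant-day, a wear window (08:00-20:00 by
default), one or two out-of-home outings from a home location to points of
interest, and the posture/activity timeline consistent with those
movements. Its design choices:

* **Trips.** Legs are piecewise constant-speed great-circle segments.
  POIs within 2 km are reached on foot at 3-6 km/h; farther POIs by vehicle
  at 30-60 km/h. POI dwells last at least 6 min and home dwells at least
  40 min, so every planted stop exceeds the 5-min/75 m detection threshold
  and every planted trip exceeds 3 min/100 m: a correct detector must
  recover all of them from noise-free data. The ground truth also records,
  per device, the *detectable* trip window — the fixes outside the 75 m
  stop neighbourhoods — because no detector observing a sampled track can
  resolve the within-radius approach and departure seconds.
* **GPS error.** Isotropic Gaussian noise in the local tangent plane
  (default 3 m, matching the reference logger's published precision) and
  i.i.d. Bernoulli dropout (default 2%). Sampling intervals are 5 s for the
  reference logger and 20/10/5 s for the watch configurations.
* **Accelerometry.** Gravity encodes posture (thigh longitudinal axis
  vertical when standing, horizontal when sitting/lying); walking adds a
  sinusoid-plus-harmonic at the scheduled cadence with exactly one peak per
  step; sensor noise is Gaussian (default 0.05 g); non-wear blocks are
  perfectly motionless. With zero noise the static vector magnitude is
  exactly 1 g.
* **Diaries.** Rows mirror the planted schedule with Gaussian reporting
  error on times (default SD 2 min) and exact self-counted steps for the
  walk task (50-100 steps).
* **Determinism.** Every quantity derives from the scenario seed through
  fixed substreams per (participant, day, channel), so identical
  configurations are byte-identical across reruns, and all devices observing
  one participant-day share one underlying truth.

What the generator does **not** emulate — multipath and urban-canyon GPS
drift, duty-cycling driven by activity recognition, soft-tissue artefacts,
device clock drift, non-wear that is moved rather than motionless, and
diary recall failures beyond time jitter. Passing the synthetic recovery
tests therefore demonstrates algorithmic correctness under the stated error
model, not field accuracy on real deployments.

## Problem sizes and numerical choices

The validation suite runs segmentation recovery on 100 noise-free and 100
noisy (10 m) participant-days, hull checks against a brute-force
edge-enumeration oracle on 100 random point sets (n ≤ 30, relative
tolerance 1e-9), non-wear checks against the window oracle on 1,000 random
1,440-epoch days, paired-test calibration on 1,000 null replicates at
n = 100, posture recovery on twenty 5-min sit/stand task pairs, step
recovery on one hundred 80-step walks, and a full 25-participant × 3-day
end-to-end study compared byte-for-byte across reruns. These sizes give
stable estimates of the recovery rates while keeping a complete run on a
single CPU within minutes.

Filters use reflected-edge padding to suppress start-up transients;
quantile-based thresholds use R's default (type 7) quantile; the trailing
partial epoch of a stream is flagged and excluded from wear/intensity
summaries; degenerate geometry (single fixes, collinear days) yields
flagged zero-valued summaries rather than errors.

## Known limitations

* Trip frequency can be summarised per day or per multi-day protocol; both
  aggregations are emitted because the pairing unit materially changes the
  statistic.
* Percent agreement on near-zero reference values is unstable; pairs with a
  zero reference are excluded with a warning.
* The stay-point scan is stop-greedy: a trip that begins and ends within
  75 m of the same dwell centroid (a short loop) is absorbed into the stop.
* Posture classification assumes a calibrated axis convention; a device
  mounted sideways would need the `long_axis` parameter adjusted.

## A worked example

```{r example, eval = FALSE}
sc <- scenario_config(n_participants = 5, n_days = 2, seed = 42)
report <- run_study(study_config(scenario = sc))
print(report)
write_report(report, "validation_out")
```
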