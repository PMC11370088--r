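---
title: "Quantifying sampling-interval bias in fine-scale GPS tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sampling-interval bias in fine-scale GPS tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackbias)
```

## The problem

Movement metrics derived from GPS fixes are scale-sensitive. Two opposing
errors depend on the sampling interval $k$:

* **measurement error** — at very frequent sampling (1–5 s) positional
  jitter of a few metres compounds across thousands of short steps and
  *over*estimates distance moved;
* **interpolation error** — at coarse sampling the straight line between
  distant fixes cuts across the real, curved flight path and
  *under*estimates it, the more so the more sinuous the flight.

For dynamic-soaring seabirds (albatrosses and petrels), whose flight
oscillates in heading and speed on a scale of seconds, both effects are
substantial, and behavioural states inferred from step speed and turning
angle shift with $k$ as well. `trackbias` implements the full pipeline for
quantifying these biases from 1 Hz logger data or from synthetic tracks
with known ground truth.

## Reference distance

At a 1-s interval, distances computed from consecutive positions are
dominated by positional error, but the *Doppler point speed* reported by
the receiver is derived from satellite signal frequency shifts and is
essentially free of positional error. The reference path $F_0$ therefore
keeps the native fixes but takes each step's distance as
$d^0_i = v_i \,\Delta t$ from the point speed $v_i$; the actual path length
is $D_0 = \sum_i d^0_i$. `stationary_error_summary()` reproduces the
validation experiment behind this choice: for loggers left at a fixed
position, the cumulative displacement-derived error is compared with the
cumulative point-speed-derived error by a Welch two-sample *t*-test on
log-transformed totals (`stats::t.test`).

## Path preparation

`clean_path()` drops duplicate timestamps (first kept) and, optionally,
fixes inside a user-supplied land-mask polygon. `interpolate_gaps()` fills
the occasional 2-s interval that low-cost loggers produce (a few percent of
fixes) by linear interpolation so the reference path is uniform at 1 s;
longer gaps are left and act as flight breaks. `segment_flights()` marks
non-flying periods where the 10-s rolling mean speed stays below 10 km/h
for at least 60 s, removes them, and returns the remaining contiguous runs
as flights. The rolling window is *centred* with partial windows at the
edges; the convention is configurable since either alignment is defensible,
and the centred form treats accelerations and decelerations symmetrically.
Doppler point speed is used as the rolling-speed source when present (it is
far less noisy than positional step speed); positional speed is the
documented fallback.

Each flight gets a straightness index
$\mathrm{SI} = \text{great-circle displacement} / \text{path length} \in
[0, 1]$. `select_si_threshold()` builds the cumulative "percent of flights
with SI below $t$" curve on a 0.01 grid and places the straight/sinuous
threshold at the knee: the grid point maximizing the discrete second
difference of the 5-point-smoothed curve. Ties are broken toward the
*higher* threshold. With a bimodal SI ensemble the second-difference peaks
at the foot of each mode can tie exactly; taking the lower tie would put
the threshold below the sinuous mode and classify everything as straight,
defeating the curve's purpose, while the higher tie lands at the foot of
the dominant rise — which is how the published version of this curve is
read. All great-circle quantities use the haversine formula on a sphere of
radius 6,371,000 m; at flight scales the spherical/ellipsoidal difference
is far below every tolerance used here.

## Sub-sampling and the bias metrics

`subsample()` re-expresses a flight at interval $k$: positions at exact
multiples of $k$ from the flight start, linearly interpolated in lon/lat
between the bracketing fixes (at 1 Hz steps are tens of metres, so
planar-vs-spherical interpolation differences are negligible; a
snap-to-nearest-fix option exists). Step distance is great-circle, step
speed is distance$/k$, and relative turning angles come from successive
step bearings, normalized to $(-180^\circ, 180^\circ]$.

The headline metric is the proportional distance
$\mathrm{PD}_k = D_k / D_0$, where $D_k$ is the sub-sampled path length.
$\mathrm{PD} > 1$ is overestimation, $< 1$ underestimation. When $k$ does
not divide the flight duration the sub-sampled path ends
$\lfloor\text{duration}/k\rfloor \cdot k$ seconds in; $D_0$ is restricted
to that same span so numerator and denominator always describe the same
stretch of flight. (Dividing by the full-flight $D_0$ instead would leave a
jagged truncation artifact at awkward $k$ and break the exact
$\mathrm{PD} \equiv 1$ identity on noise-free geodesic tracks.)

Per-point errors are computed per sub-sampled step $j$ against the
reference steps falling inside it:

* $\mathrm{PE}_{dist,j} = |\sum_{i \in w_j} d^0_i - d_j|$ (m),
* $\mathrm{PE}_{speed,j} = |\overline{v}_{w_j} - d_j/k|$ (m/s),
* $\mathrm{PE}_{angle,j} = \big|\,\overline{|\theta^0|}_{w_j} -
  |\theta_j|\,\big|$ (degrees),

with distance/speed windows $[t_j, t_{j+1})$ keyed by reference-step start.
Angle windows are half-open on the other side, $(t_j, t_{j+1}]$, and
$\theta_j$ is the turn at the step's end fix: with this convention $F_1$
reproduces $F_0$'s turns exactly and $\mathrm{PE}_{angle} \equiv 0$ at the
native interval, whereas strictly-open windows would be empty there.
Absolute values are stored for all three metrics (the published curves are
magnitudes) alongside the signed reference-minus-sub-sampled differences,
which cost nothing and preserve direction. With 1-s references this makes
$\mathrm{PE}_{dist} = k \cdot \mathrm{PE}_{speed}$ identically, a
consistency check in the test-suite.

`aggregate_bias()` averages PD at the flight level and the PE metrics at
the point level, per $k$ and per group. PD aggregation over flights (not
pooled points) is the default since flights are the independent units; it
is configurable through the grouping column. Degenerate cases: a single
flight has undefined SD (reported `NA`), identical flights give SD 0.

## Behavioural states and their spatial stability

`fit_hmm()` fits a 3-state hidden Markov model to the bivariate series
(step speed, absolute turning angle) with independent Gaussian emissions
per state, by EM with scaled forward–backward recursions. Angles enter as
absolute values, matching the magnitude convention of
$\mathrm{PE}_{angle}$; the signed alternative is a one-line change but
would demand a circular emission family to be coherent. Gaussian emissions
are the deliberate default even though a Gamma (speed) / von Mises (angle)
pair is distributionally more natural — the Gaussian variant is the one
whose sampling-interval sensitivity is being characterized. Numerical
choices: 10 EM restarts seeded from k-means partitions with a fixed seed
stream (the fit is deterministic given `seed` and does not disturb the
caller's RNG), convergence at relative log-likelihood change $10^{-8}$ (cap
200 iterations), and an emission-SD floor of $10^{-3}$ guarding degenerate
states such as exactly-zero speeds at fine intervals; zero-inflation is
intentionally not modelled. `label_states()` names states by mean speed
(lowest = rest, highest = commute, middle = forage), warns when forage
lacks the largest mean angle, and breaks speed ties by angle (lower angle
= commute). Decoding is global Viterbi by default, with per-point
posterior argmax as an option.

`kernel_ud()` builds each state's utilization distribution: positions are
projected with an azimuthal-equidistant projection about the trip centroid
(distances from the centre exact, which is what a kernel cares about), then
smoothed with a Gaussian product kernel at the reference bandwidth
$h_{ref} = 0.5\,(s_x + s_y)\, n^{-1/6}$ on a 200×200 grid padded 10% beyond
the point extent (plus $3h$ so no kernel mass is clipped), renormalized to
integrate to 1. The 50% kernel is the smallest density-threshold set
holding half the mass. `overlap_vi()` computes the volume of intersection
$\mathrm{VI} = \sum_{cells} \min(\mathrm{UD}_a, \mathrm{UD}_b)\,\Delta A$;
on normalized UDs this is 1 for identical and 0 for disjoint
distributions. `state_stability_curve()` refits the HMM *per* interval
(fresh fit, shared seed) — refitting is what an analyst at that interval
would do — and compares every pair of intervals' forage UDs on one common
grid; both the full-UD overlap and the 50% contour are available, the
overlap being computed on full UDs where the min-integral is
well-defined.

## The synthetic-data generator

`gen_track()` integrates a speed/heading process on the sphere in 0.1-s
great-circle substeps, so generator and analyzer share one distance
convention, then samples 1 Hz fixes. Regimes: `straight` (constant
heading), `soar` (heading $= h_0 + A\sin(2\pi t/T)$, the dynamic-soaring
signature; defaults $A = 60^\circ$, $T = 10$ s), `circle` (constant turn
rate from a radius, the closed-form test geometry), `rest` (slow drifting
random walk around 0.3 m/s). Observation noise matches the magnitudes
reported for the logger class being emulated: isotropic positional jitter
of SD 5 m, point-speed error SD 0.0075 m/s (mean absolute error 0.006
m/s), and 2-s gaps on 2% of intervals by default (10% reproduces deployed
loggers). Gaps are generated on the *interval* sequence — each inter-fix
interval is independently 2 s with the configured probability — so gaps
are always isolated and short-gap interpolation restores the exact uniform
path, and the realized 2-s fraction is binomial around the configured
rate. `gen_stationary()` fixes the true position; `gen_trip()` assembles a
labelled >24 h central-place foraging trip (commute out, two compact
foraging patches worked in paired opposite-heading soaring bouts with
rests, a long night rest, commute back) with ground-truth states and patch
centres for recovery tests.

What the generator deliberately does not emulate: autocorrelated GPS error
(real positional error is strongly autocorrelated; white jitter makes the
fine-interval measurement-error regime *harsher* than reality), wind
drift, zero-speed spikes from fix failures, and species-level variation in
flight style. Passing tests therefore demonstrate the pipeline's
correctness and the direction and rough magnitude of the biases under
clean assumptions, not the field error budget of any particular logger.

## Problem sizes and tolerances

The test-suite runs at desk scale by choice: 2-h synthetic flights,
cohorts of ~20 flights, $k$ grids of tens of values, an HMM recovery
series of $n = 2000$, and a one-day trip at three to six intervals. The
closed-form circle checks use $r = 100$ m, $v = 10$ m/s, where
$\mathrm{PD}_{10} = \sin(0.5)/0.5 \approx 0.9589$ and the per-step polygon
turn gives $\mathrm{PE}_{angle} \approx 51.57^\circ$; these are asserted
to $10^{-3}$ relative. Geometric identities on simulated "straight" tracks
are asserted to $10^{-6}$ (PD) — the residual is the curvature of the
numerically integrated path, not the analyzer.

## Known limitations

* The land mask is a simple even-odd polygon test in lon/lat; masks
  straddling the antimeridian need pre-splitting.
* The HMM assumes Gaussian emissions and no zero-inflation; at very fine
  intervals over water rest periods produce near-zero speeds that the SD
  floor absorbs but does not model.
* Kernel UDs ignore serial autocorrelation, which inflates apparent
  precision at fine intervals — exactly the regime this package is used to
  characterize, so the overlap curves should be read comparatively, not as
  home-range estimates.
* SI is computed on the observed (jittered) path; at 1 Hz the jitter
  inflates path length and so deflates SI slightly — visible in the
  synthetic cohort, and equally present in real 1 Hz data.
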