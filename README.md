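# trackbias

Sampling-interval bias in fine-scale GPS tracking of flying seabirds.

GPS loggers small enough for albatrosses and petrels can record a fix every
second, but most deployments sample far more coarsely to save battery.
Movement metrics computed from fixes are scale-sensitive in two opposing
ways: at very short intervals (1–5 s), ~5 m positional jitter compounds
across thousands of tiny steps and **over**estimates distance moved, while
at long intervals the straight line between fixes cuts across the real,
curved flight path and **under**estimates it — severely so for the sinuous
paths of dynamic-soaring seabirds. `trackbias` is for movement ecologists
who need to quantify those biases, compare tracks collected at different
rates, or decide what a chosen sampling interval does to inferred
behaviour.

## What it computes

Given 1 Hz fixes (or synthetic stand-ins with known ground truth), the
package:

* validates Doppler **point speed** as a reference distance
  (stationary-logger error summary with a Welch *t*-test on log totals);
* cleans paths, interpolates single 2-s gaps, segments **flights** (10-s
  rolling mean speed < 10 km/h sustained ≥ 60 s marks non-flight), and
  classifies them straight vs. sinuous by a **straightness index**
  threshold chosen at the knee of the cumulative SI curve;
* builds the reference path F₀ with step distances `d⁰ᵢ = vᵢ·Δt` from
  point speed (actual length `D₀ = Σ d⁰ᵢ`), sub-samples each flight at
  intervals k = 1…3600 s, and computes the **proportional distance**
  `PDₖ = Dₖ / D₀` (> 1 overestimate, < 1 underestimate) plus per-point
  errors `PE_dist`, `PE_speed`, `PE_angle` against the reference steps
  inside each sub-sampled step, aggregated into mean ± SD curves per
  flight class and species;
* fits a **3-state Gaussian HMM** (rest / forage / commute) on step speed
  and absolute turning angle at each interval, builds per-state kernel
  utilization distributions (`h_ref = 0.5·(s_x + s_y)·n^(−1/6)`), and
  measures spatial stability across intervals with the
  **volume-of-intersection** overlap `VI = Σ min(UD_a, UD_b)·ΔA`.

## Worked example

Twenty-minute read: simulate a small cohort of straight and soaring
flights (2 h each, 5 m jitter, 2% dropped fixes), run the bias analysis on
a coarse k grid, and correct a reported trip distance.

```r
library(trackbias)

run <- run_bias_analysis(list(seed = 1,
  simulate = list(n_straight = 5, n_sinuous = 5, duration = 7200),
  bias = list(k_max = 600, k_step = 60)))
run
#> <bias_run> 10 flights (10 above duration cutoff), SI threshold 0.87
#>   flight_class n_flights mean_pd_over_60s k_max_pe_angle
#> 1      sinuous         5        0.7440885            540
#> 2     straight         5        0.9999964            300
```

The SI knee lands at 0.87, splitting the cohort 5/5. Straight flights are
essentially unbiased beyond k = 60 s (mean PD ≈ 1.000), while the soaring
flights lose a quarter of their true path length (mean PD ≈ 0.744): a
track sampled every 10 minutes simply cannot see heading oscillations with
a 10-s period. Inverting the bias corrects a reported distance:

```r
correct_trip_distance(11000, pd = run$report$mean_pd_over_60s[["sinuous"]])
#> [1] 13815.03
```

i.e. an 11,000 km trip logged at this cohort's sinuosity would really be
~13,800 km of flight. The same inversion with the published long-interval
biases for straight (10%) and extremely sinuous (40%) flight gives
12,100 km and 15,400 km.

Behavioural-state stability on a labelled synthetic foraging trip:

```r
trip <- gen_trip(seed = 1)
sc <- state_stability_curve(trip$path, k_grid = c(600, 1200, 1800),
                            seed = 1, n_restarts = 5)
sc
#> <overlap_curve> forage-state VI over 3 intervals (k = 600-1800 s)
#>   600  1200  1800
#> 0.835 0.784 0.809
```

Each number is the mean VI overlap between that interval's forage-state
kernel and the other intervals': the foraging picture drifts as the
sampling interval changes even on the same trip.

A thin command-line front end lives at `inst/cli/trackbias.R`
(`simulate`, `bias`, `states`, `all` verbs); the methods vignette
(`vignettes/sampling-interval-bias.Rmd`) documents the model choices,
defaults and tolerances.

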