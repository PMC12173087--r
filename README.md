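# crowdtrack

Visual crowding — the difficulty of recognising a peripheral target when
clutter surrounds it — is classically measured with slow, trial-based
forced-choice experiments. Continuous target-tracking psychophysics offers a
faster alternative that also exposes the *temporal* dynamics of crowding: an
observer continuously matches the orientation of a rotating Landolt-C target
while the distance between the target and a surrounding flanker ring sweeps
over time, and sudden orientation reassignments ("jump points") probe how
quickly tracking recovers from a disruption.

`crowdtrack` implements that paradigm end to end for simulation studies and
analysis development:

- **Stimulus generation** — orientation trajectories at 144 Hz (72°/s
  rotation, direction re-drawn at each jump), 0.13°/s target–flanker
  distance sweeps over 0–5°, jump scheduling at preselected distances,
  flanker-gap assignment (first gap ~ Normal(target, 45°), others at 90°
  intervals), block schedules (8 flanked + 4 isolated trials) and a
  200-trial trial-based session.
- **Synthetic observers** — motor latency, distance-dependent circular
  report noise with a hinge at the true crowding extent
  σ(d) = σ₀ + s·max(0, e_c − d), and condition-specific exponential
  recovery from jumps.
- **The analysis chain** — wrapped report errors in [−180°, 180°);
  isolated-condition artifact cleaning (peaks above 2 SD, segments above
  mean + 1 SD deleted from both conditions); tracking performance as the
  cosine similarity, which reduces to (1/n)·Σᵢ cos(θ_stimulus,i −
  θ_response,i); crowding extent from the intersection of flanked and
  isolated error-versus-distance regression lines, and from a hinged-line
  fit; perceptual error as the circular SD √(−2 ln R̄) of a
  maximum-likelihood Von Mises fit; post-jump recovery by fitting
  E(t) = a·e^(−bt) + c (with and without a ~280 ms motor-delay correction);
  recovery time by sequential t-tests against the stable baseline.
- **Group statistics** — paired t-tests with Cohen's d, 2×2
  repeated-measures ANOVA with partial η², Pearson correlation.

Everything is a plain function over data frames, returning tibbles, with
broom-style `tidy()`/`glance()` methods and ggplot2 plot builders.

## Worked example

Simulate eight synthetic observers (two continuous runs plus one
trial-based session each) under the default paradigm and analyse them:

```r
library(crowdtrack)

observers <- lapply(1:8, function(i) observer_config(seed = 100 + i))
ds  <- generate_dataset(paradigm_config(), observers, n_runs = 2, seed = 1)
res <- analyze_dataset(ds)
res
#> Crowding analysis
#>   observers: 8, continuous runs: 16
#>   tracking performance: isolated 0.985, flanked 0.822 (means)
#>   crowding extent (intersection): continuous 4.97 deg, trial-based 4.78 deg (means)
#>   recovery rate b: isolated 2.00 /s, flanked 1.13 /s (means)
#>   pooled recovery time: isolated 1062 ms, flanked 1667 ms
```

Flankers reduce tracking performance (cosine similarity 0.82 vs 0.98), the
two paradigms agree on the crowding extent of the generating observers
(hinge at 5°; the regression-intersection estimate is 4.97° continuous and
4.78° trial-based, and the per-observer estimates correlate at r = 0.80,
`res$group$r_extent_paradigms`), and post-jump errors shrink more slowly
when flanked (the uncorrected rates shown are dragged down by the motor
dead time; the motor-corrected fits in `res$runs$b_isolated_corrected` /
`b_flanked_corrected` sit near the generative 3.5 and 2.0 /s).

Per-run detail lives in `res$runs` (one row per observer × run),
`res$trial_based`, and `res$details`; group tests in `res$group`. For
figures:

```r
one_run <- analyze_continuous_run(dplyr::filter(ds$continuous, observer == 1, run == 1))
plot_error_vs_distance(one_run)
ggplot2::autoplot(one_run$fits$decay$isolated_corrected, data = one_run$windows$isolated)
```

File-based workflows mirror the same steps: `run_simulate()` writes
per-observer CSVs plus a hashed manifest, `run_analyze()` emits
per-participant and group JSON reports, and `run_recover()` tabulates
parameter-recovery studies (true crowding extent or recovery rate against
their estimates).

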