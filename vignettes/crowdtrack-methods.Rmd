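---
title: "Methods: simulating and analysing continuous crowding tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing continuous crowding tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crowdtrack)
```

## The paradigm

A Landolt-C target at 10° eccentricity rotates at 72°/s (0.5° per frame at
144 Hz) for 40-s trials, giving 5760 samples per trial. In flanked trials a
four-gap ring surrounds the target; the edge-to-edge target–flanker distance
sweeps at 0.13°/s between 0° and 5°, starting at whichever end matches the
trial's trend. When the sweep reaches one of five preselected distances
(0.31°, 0.35°, 1.35°, 2.20°, 3.37°) all gap orientations are reassigned at
random and the rotation direction is re-drawn — a "jump". Isolated trials
have no visible flanker but inherit the matched trend's distance trace and
jump times, so the two conditions are comparable frame by frame. A block
holds 8 flanked trials (half increasing, half decreasing distance) and 4
isolated trials in random order. The companion trial-based session presents
static stimuli at the seven flanked distances plus isolation, 25 repetitions
each (200 trials).

Two notes on the jump distances. The list is kept verbatim as the default;
the geometric construction (log-spaced between 0.8° and 5.8°, then
re-expressed relative to touching) yields a different set and is available
as `log_spaced_jump_distances()` for users who prefer the generative rule.
And because the 0.13°/s sweep covers 5.2° in 40 s while the range is 5°, the
trace clamps and holds at the boundary — the physically sensible behaviour
for stimuli that cannot overlap or leave the annulus.

Wrapping conventions are fixed once: orientations live in [0°, 360°),
differences in [−180°, 180°) with the antipodal tie resolved to −180°.

## The synthetic observer

The observer model exists to make the analysis chain's estimators correctly
specified, so that parameter recovery is a meaningful test of the chain.
Three components:

1. **Report noise.** An Ornstein–Uhlenbeck orientation-noise channel with
   correlation time 300 ms and stationary SD
   σ(d) = σ₀ + s·max(0, e_c − d), where σ₀ = 10° is the uncrowded baseline,
   s = 8°/° the crowding penalty, and e_c the true crowding extent (default
   5°, the full tested range). The temporal correlation reproduces the
   smooth error autocorrelation of real mouse traces; the hinge is exactly
   the quantity the extent estimators target. Trial-based reports draw from
   a Von Mises with κ = 1/σ(d)² (σ in radians) — the standard large-κ
   correspondence. For large σ this mapping under-concentrates slightly (at
   σ = 50° the implied circular SD is ~62°), which makes the generative
   noise profile mildly convex in σ; the hinge location itself is
   unaffected, and the approximation is exact where it matters for the
   baseline (σ₀ = 10° maps back to 10.07°).

2. **Pursuit.** The smooth rotation is fully predictable, and the observer
   follows it with a velocity-matched, lag-compensating pursuit: the
   first-order motor lag (time constant 150 ms) produces no steady-state
   error on a constant-velocity ramp. This is the standard reduction of a
   predictive tracker and it is what makes the steady-state report error
   carry σ(d) undistorted — a non-predictive delayed tracker would add a
   ±31° direction-signed offset (72°/s × 430 ms) that swamps the crowding
   signal and breaks every σ-recovery property.

3. **Jump recovery.** At a jump the report error instantly becomes the
   wrapped offset between the projected old course and the new orientation
   (the error is imposed by the stimulus, not the hand). The observer
   re-identifies the target after the 280 ms motor latency plus an
   exponential waiting time with the condition's recovery rate
   (b = 3.5 /s isolated, 2.0 /s flanked). With this "search then snap"
   mechanism the mean absolute error after a jump is *exactly* affine in
   e^(−bt): the decay fit E(t) = a·e^(−bt) + c is correctly specified. The
   alternative — a per-jump deterministic exponential of the signed error —
   looks more natural but makes the mean *absolute* error non-exponential
   near the noise floor (|·| is convex), inflating fitted rates by 15–20%
   at the default rates; we verified this on noiseless ideal curves. The
   cost of the snap model is sampling variance: each jump contributes one
   waiting-time draw, so a 50-jump recovery estimate has a sampling SD of
   roughly 15% of the true rate. The package's recovery harness therefore
   reports replicate 50-jump estimates; their central tendency is unbiased.

What the generator does **not** emulate: fixation breaks and blinks (the
`gap_mask` column exists in the data format but defaults to all-FALSE),
saccade or attention dynamics, motor-output noise separate from perceptual
noise, and human-scale tracking difficulty — the default observer tracks
more accurately than people do (isolated cosine similarity ≈ 0.98 vs ≈ 0.88
for humans), because its only steady-state error source is the perceptual
noise channel. Passing tests therefore demonstrate that the estimators
recover the generative parameters under the model's assumptions, not that
they are robust to everything real data contain.

## The analysis chain and its decision points

**Report error and cleaning.** The per-frame error is the wrapped
response − stimulus difference. Artifact cleaning detects dominant peaks in
the isolated condition — frames whose absolute error exceeds twice the SD of
the isolated signed errors — and deletes, from both conditions, the
contiguous segment around each peak where the absolute error stays above the
isolated mean + 1 SD. Two interpretation choices are deliberate: the
thresholds come from the *signed* error moments (using the SD of the
absolute-error series would place the threshold below its own mean and
delete nearly everything), and detection operates on the absolute series. A
constant series (SD = 0) deletes nothing. Cleaning is computed per
trial-pair, each flanked trial keyed to an isolated trial of the same trend.
Under the defaults this removes ~4–8% of frames per trial, consistent with
the ~10% reported for human data. Cleaning is applied before
flip-and-average; the reverse order is a sensitivity question the data
format supports but the pipeline does not assert.

**Post-jump windows are extracted from uncleaned errors.** The cleaning rule
targets exactly the large post-jump excursions whose decay the recovery
analysis measures; applying it first would delete the signal. The tracking
performance and extent analyses use cleaned data; the decay and
recovery-time analyses use raw windows (300 samples ≈ 2080 ms, never
crossing the next jump; the motor-corrected variant drops the first 40
samples ≈ 280 ms).

**Tracking performance.** Cosine similarity over pooled cleaned frames.
The printed sum-over-products form reduces algebraically to the mean cosine
of the report error; the identity is asserted to 1e−12 in the tests.

**Crowding extent, two estimators per paradigm.**
`method = "intersection"` is the conventional analysis: OLS lines through
flanked and isolated error-versus-distance data (flip-averaged absolute
errors for the continuous paradigm; per-distance Von Mises circular SDs for
the trial-based one), intersected with each other or with the flat isolated
baseline. This estimator is consistent when the true extent equals or
exceeds the largest tested distance — the regime the defaults occupy — but
is structurally biased for interior extents, because the flanked data are
flat above the hinge and a single line through sloped-plus-flat data crosses
the baseline too far out (closed form: ~+0.9° at e_c = 3, ~+1.6° at e_c = 2
for a uniform sweep). `method = "hinged"` fits the broken-stick model
σ(d) = baseline + s·max(0, h − d) by profiling h on a 0.01° grid (the slope
has a closed form given h) and is consistent for interior hinges; the
parameter-recovery tests use it. For the continuous paradigm the hinged
variant estimates σ(d) as the pooled circular SD of signed errors within
0.25° distance bins, split by rotation direction (circular SD is
location-free, so any direction-signed offset drops out), and excludes
frames within the 300-sample post-jump window — those frames measure
temporal reacquisition, not spatial crowding, and because the flanked
condition recovers more slowly than the isolated condition that drives the
cleaning mask, their residuals would otherwise leak into the profile.

**Decay fit.** Bounded Levenberg–Marquardt (a, b, c ≥ 0) with starting
values a₀ = first-sample − tail mean, b₀ = 1 /s, c₀ = tail mean, and five
jittered restarts on failure; tolerance 1e−10, 500 iterations. A constant
input short-circuits to (a, b, c) = (0, 0, mean). Shifting the time origin
(the corrected variant starts at 280 ms) rescales only a, never b.

**Recovery time.** The last 50 window columns form the stable pool; Welch
two-sample t-tests (unequal n and variance between one column and the pool)
scan forward from the jump, and the first non-significant column (α = 0.05,
no multiple-testing correction — a faithful-replication choice) is the
recovery time. If no column qualifies the window end is reported with a
flag. Both a per-participant and a pooled-across-participants variant are
available, since the original description supports either reading.

**Group statistics.** The 2×2 repeated-measures ANOVA computes
within-subject sums of squares directly and tests each effect against its
own subject-by-effect interaction, F(1, n−1), with partial η² as the effect
size; sphericity is moot for single-df effects. The implementation is
cross-checked against `aov()` + `Error()` strata in the tests.

## Problem sizes and runtime

The default simulated study is 8 observers × 2 continuous runs × 12 trials
(5760 frames each) plus 8 × 200 trial-based reports — about 1.1 M tracking
frames, generated in a few seconds and analysed in a few more on one core.
Parameter-recovery studies regenerate that dataset per grid point (true
extents 2°, 3.5°, 5°) and use 10 trials (50 jumps) per recovery-rate
replicate. All randomness flows from one root seed through a small integer
hash, so every trial, observer and run is independently reproducible and
end-to-end reruns are byte-identical.

## Known limitations

- The regression-intersection extent estimator inherits the interior-hinge
  bias described above; report it alongside the hinged estimate when the
  extent may lie inside the tested range.
- Recovery-rate estimates from a single run (20–40 jumps) are noisy; the
  group-level ANOVA across observers is the intended inferential unit.
- The recovery-time orderings of the default observers need not match human
  data: in people the flanked condition's higher baseline masks the jump
  error and shortens measured recovery despite a lower decay rate, a
  masking effect whose size depends on baseline-to-jump-error ratios the
  default observer does not attempt to match. The mechanism itself —
  higher flanked baseline, lower flanked rate — is reproduced and tested.
- Deleted frames are deleted, never imputed; downstream means simply skip
  them.
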