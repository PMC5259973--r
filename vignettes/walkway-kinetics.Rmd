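---
title: "Walkway kinetics for a unilateral forelimb pain model: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walkway kinetics for a unilateral forelimb pain model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pswalk)
```

## The measurement problem

A pressure-sensitive walkway (PSW) records, at 60 Hz, a grid of calibrated
vertical forces (here 4 sensels/cm^2 over a 2.4 m x 0.5 m mat, 50 psi range).
When a cat walks across the mat or lands on it after jumping from a perch,
each paw contact appears as a compact blob of loaded sensels lasting a handful
of frames. From each contact we want two normalized kinetic quantities:

* **PVF** (peak vertical force), the maximum of the contact's force--time
  curve, as a percentage of body weight;
* **VI** (vertical impulse), the time integral of that curve, in %BW·s.

In a unilateral forelimb pain model (one declawed forepaw per study period),
the scientific signal is *asymmetry* between the operated (OP) and
non-operated (NO) forelimb, summarized by the symmetry index

$$ SI = \frac{x_{op} - x_{no}}{\tfrac12 (x_{op} + x_{no})} \times 100, $$

which is 0 under perfect symmetry, negative when the operated limb is
unloaded, and −200 at complete non-weight-bearing. Landing trials add timing
metrics: `tf1f2`, the signed lag between operated and non-operated forelimb
strikes (positive = delayed loading of the painful limb); `NTf1f2`, the count
of trials in which that lag is *measurable*, i.e. at least one frame
(1/60 s ≈ 0.017 s); and `tf1h1`, the delay from first forelimb to first
hindlimb strike.

The package implements the full chain — synthetic data generation, footfall
extraction, trial quality control, kinetic summaries, and the crossover
statistics — so that every stage is testable against known ground truth
without access to proprietary walkway software or animal data.

## The synthetic-data generator

`simulate_study()` emulates a two-period crossover in four cats
(2.2–3.2 kg): per cat and period, two baseline sessions (−48, −24 h), six
post-operative kinetic sessions (6, 24, 30, 48, 54, 72 h) with ten walking
and ten landing trials each, and ordinal 0–5 pain scores at
3, 6, 12, 24, 30, 36, 48, 54, 60, 72 h. The default allocation
(`default_allocation()`) alternates treatment sequence and operated foot
across cats exactly as a balanced two-sequence schedule requires.

Design choices a user should know about:

* **Force-curve family.** Contacts are half-sine force--time curves (with a
  triangular alternative in `generate_force_curve()`), chosen because their
  integrals are analytic: VI = (2/π)·PVF·T for the half-sine and PVF·T/2 for
  the triangle. Curves are sampled at frame midpoints, so every contact frame
  carries positive force; the ground-truth VI is defined as the frame-grid
  integral of the sampled curve (the midpoint rule, which equals the
  trapezoid over the zero-padded frame grid). The extractor integrates the
  same way, making generator and extractor comparable without an arbitrary
  sub-frame convention.
* **Magnitudes.** Walking peaks default to 55 %BW (fore) and 45 %BW (hind),
  in the range reported for walking cats. Landing forelimb peaks default to
  187 %BW with an 8% coefficient of variation and a 0.125 s contact, chosen
  once so that baseline landing PVF sits near 185–190 %BW and VI near
  15 %BW·s — the scale of published landing tables for cats jumping from
  0.7 m. Peaks scale with √(h/0.7) for other perch heights.
* **Lameness.** A per-arm, per-time multiplier in [0, 1] scales the operated
  forelimb's peak (1 = sound). The default control profile drops to ≈0.5 with
  partial recovery; the treated arm is uniformly less lame. No compensatory
  increase is applied to the contralateral forelimb, so the generator
  contract is that the OP/NO peak ratio equals the lameness factor; the
  redistribution of load onto the non-operated limb seen in real animals is
  deliberately not modeled (it would make the planted ratio unrecoverable).
* **Landing timing.** The inter-forelimb stagger is 1–2 frames with
  probability 0.24 at baseline, rising by 0.5·(1 − lameness); at a lameness
  of 0.5 this gives ≈0.49, matching the scale of reported measurable-stagger
  rates (19/78 baseline vs 59/120 post-operative). When lame, the operated
  limb strikes later; at baseline the sign is random. The fore-to-hind delay
  is 0.11 s at baseline plus 0.06 s per unit lameness.
* **Walking gait.** A lateral-sequence walk (LF, RH, RF, LH at quarter-stride
  phases) with 0.40 m strides and duty factor 0.55; hind paws land on the
  ipsilateral fore print (track-up), which is also what the limb classifier
  exploits. Trial velocity is log-normal around the 0.6 m/s target with a
  spread chosen so that a realistic fraction of trials violates the
  0.6 ± 0.2 m/s window and exercises the QC stage.
* **Footprints and noise.** Each paw is rendered as a truncated-Gaussian
  pressure blob (σ = 0.75 cm over a 9 × 9-sensel window, ≈3 × 3 cm), with
  weights normalized so the blob's summed force reproduces the planned curve
  exactly. Sensel noise is multiplicative — mean-one log-normal with a 5%
  log-scale SD — because piezoresistive sensels show load-proportional
  noise, unloaded sensels read zero, and no clamping is ever needed. (An
  additive-noise model was rejected: clamping additive noise at zero force
  over a footprint's many near-zero sensels biases integrated forces upward
  by several percent, violating the extractor's oracle-equivalence contract
  of VI within 2% and PVF within one frame's force change.) The default
  detection threshold, 0.02 N, is twice the noise of a sensel carrying
  ~0.4 N and far below any paw's centre-sensel load.
* **Pain scores.** A latent post-surgical intensity `A·exp(−t/τ)` (control:
  A = 2.0, τ = 40 h; treated: A = 0.9, τ = 18 h) plus bounded uniform
  observation noise (±0.4), rounded and clamped to 0–5. Bounded noise makes
  the defaults *deterministically* respect the observed ceiling of 2 — no
  simulated cat ever triggers the rescue-analgesia threshold of 4 — while
  other configurations can exceed it.

Two generation paths share one stochastic model: the session planners draw
all quantities vectorized per session, and `render_frames = TRUE` turns each
planned trial into a sparse pressure recording. The footfall-level fast path
(the default) simply skips rendering and computes the sampled PVF/VI in
closed form; tests assert the two paths agree exactly. A full study is 1280
trials, so statistical work (e.g. 200-replicate calibration) uses the fast
path, while extraction-oriented checks render on the order of 100 trials.

### What the generator does not emulate

Real mats drift, saturate, and carry structured (non-independent) noise; cats
decelerate, wander, and place paws with overlapping pads; lameness changes
contact geometry, not just peak force. Passing tests therefore demonstrate
the *pipeline's* correctness against a controlled model of the data, not the
field performance of the extraction heuristics on arbitrary recordings.

## Footfall extraction

`detect_contacts()` thresholds sensels, links them by 8-neighbourhood
adjacency within frames and same-or-neighbouring-sensel overlap across
consecutive frames, and merges temporally overlapping components closer than
2 cm (pads of one paw). Numerical conventions, all documented parameters:

* The event curve sums **raw** frame forces over the union footprint of the
  event, and the event span extends into neighbouring frames while the
  footprint still carries more than twice the per-sensel threshold; this
  prevents low-force loading/unloading frames from being clipped, which
  would otherwise bias VI down by several percent.
* Strike time is the first active frame, lift the frame after the last;
  contact time is `n_frames / frame_rate` — an integer multiple of 0.017 s,
  matching the 60 Hz granularity. No sub-frame interpolation is attempted.
* Events whose footprint force never exceeds ten times the threshold are
  discarded as sensor noise (a paw at minimum load is orders of magnitude
  above this).
* VI uses the trapezoid on the zero-padded frame grid (equivalently, the
  rectangle rule over contact frames), matching the generator's definition.

`classify_limbs()` labels events. Landings are forced by the protocol: the
earliest one or two strikes are forelimbs, left/right from lateral offset
(travel along +x; the cat's left is the larger-y side). For walking, side
comes from lateral position and fore/hind from the track-up property:
strikes sharing a print location within 5 cm pair as (fore earlier, hind
later), and unpaired mat-edge strikes are filled by temporal alternation
within the side. Events with lateral separation under one sensel pitch are
flagged `unclassified`. This rule is our convention — walkway software
vendors do not document theirs — and recovers ≥95% of ground-truth labels on
simulated gaits, which is the tested contract.

The PVF tolerance in the oracle-equivalence tests is the force change across
one frame of the sampled curve (≈ π·PVF/n for a half-sine spanning n
frames): a 60 Hz system cannot pin the peak tighter than what the curve does
within one frame, and sensor noise sits well inside that envelope.

## Trial quality control

Walking passes are valid when the least-squares velocity of the body's
strike positions is within ±0.2 m/s of the 0.6 m/s target, the slope of
consecutive segment velocities is within ±0.1 m/s², and the lateral
deviation from the side-wise mean path is under 10 cm (the straightness
criterion replaces the protocol's visual checks). `select_best_trials()`
keeps the five valid trials closest to the target velocity, breaking ties by
smaller acceleration magnitude and then trial order (our convention); fewer
than five yields all of them plus a warning, mirroring sessions where
animals refuse to walk. Because real cats walked faster than the a-priori
target, QC also offers a `"comfortable"` mode in which each cat's median
velocity replaces the fixed target. Landing validity needs only
forelimbs-first contact and forward travel; the acceleration bound is
applied to walking alone, since nothing suggests it was ever imposed on
landings.

## Kinetic summaries

`session_summary()` computes SI per trial and then averages within the
session (mean of ratios). The alternative — SI of the session-mean PVFs —
is not consistent with per-trial summary variability whenever trials vary,
and only the per-trial reading supports a session SD for SI; it is the
convention used throughout. `baseline_adjust()` averages each cat-period's
two baseline sessions separately (each period has its own baselines) and
subtracts that average from every post-operative value; a missing baseline
session leaves the lone session in charge and flags the rows.
`washout_readiness()` declares a cat ready for its second surgery when the
current mean PVF lies inside the inclusive 95% t-interval of the pooled
baseline trial-level PVFs — the trial-level spread is the only variance
source available, and the inclusive boundary is the documented tie-break.

## Study-level statistics

* **Pain AUC.** Trapezoid of (score − baseline) versus time, anchored at
  (0 h, 0); negative increments are kept unless `floor_negative = TRUE`.
  Arms are compared per cat with a paired t-test and the exact one-sided
  Wilcoxon signed-rank test by complete enumeration of the 2^n sign
  assignments (mid-ranks for ties). One-sidedness is deliberate: with four
  subjects the enumeration floor is 1/16 = 0.0625, the printed "0.063", and
  that floor exists only one-sided.
* **Ordinal pain model.** A proportional-odds model with treatment, period,
  time (days, numeric) and the time × treatment, time × period interactions.
  With four cats a full ordinal mixed model is fragile, so the default is
  the marginal maximum-likelihood fit with cat-clustered sandwich standard
  errors; a random-intercept fit via Gauss–Hermite quadrature (15 nodes) is
  exposed as `method = "random_intercept"`. Wald chi-square tests with so
  few clusters are approximate and anti-conservative in the extreme tails;
  the per-term tests are reported for effect screening, not confirmatory
  inference, and the vignette's own calibration probes treat them as such.
  From the fit, the probability that the score sits at the baseline level is
  traced over time per period × treatment; `crossing_time()` reports where
  each curve first reaches 0.5 (linear interpolation), `"< t_min"` when it
  starts above, `"> t_max"` when it never arrives.
* **Kinetic mixed model.** Baseline-adjusted responses are modeled with
  treatment, time (factor over the six post-op sessions) and their
  interaction as fixed effects and random intercepts for cat and for the
  cat × period series; the series intercept is what the paired baseline
  subtraction induces (all six deltas of a series share their baseline's
  noise) and is exactly a compound-symmetric within-series covariance.
  `covariance = "unstructured"` additionally tries a general 6 × 6 residual
  correlation with per-time variances; with four cats this frequently fails
  to converge and falls back, with a `psw_covariance_fallback` warning, to
  the compound-symmetry model. Overall tests use marginal (type-III-style)
  F tests under sum-to-zero contrasts; per-timepoint treatment contrasts are
  adjusted with the multivariate-t method over the six-contrast family (the
  Tukey-type correction appropriate for a two-level factor examined at each
  time), with its quasi-Monte-Carlo RNG pinned so reports are reproducible
  byte for byte. `dunnett_vs_baseline()` compares each post-operative time
  to the averaged baseline within one arm with Dunnett adjustment.
* **Stagger counts.** `chisq_2x2()` is Pearson's test without continuity
  correction (configurable) plus the cross-product odds ratio `(ad)/(bc)`,
  Haldane-corrected when a cell is zero. Orient the table rows as
  (post-operative, baseline) to express the post-op odds of a measurable
  stagger relative to baseline.

Calibration is checked by simulation: under a null crossover (both arms
given the control lameness profile) the mixed-model treatment term's type-I
error at α = 0.05 is verified to lie inside the 95% binomial band at 200
replicates of the full default study (landing trials); lighter 30-replicate
probes guard the ordinal route. These sizes keep the whole suite's
simulation budget modest while leaving the binomial bands meaningful.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config()
report <- run_pipeline(cfg, seed = 11)
report
report$crossing_times
autoplot(attr(report, "ordinal_fit"))
plot_si_timecourse(report$session_tables, "si_pvf_mean", "landing")
```

Under the default (treatment-responsive) configuration the report shows the
expected structure: strongly negative landing and walking SI after surgery,
significantly less asymmetry in the treated arm, treated-arm
probability-of-baseline curves crossing 0.5 within hours while control
curves take days, and a post-operative excess of measurable forelimb
staggers.

## Known limitations

Four subjects bound every inferential statement; the mixed models are exact
only under their covariance assumptions, and the sandwich-based ordinal
tests are approximations whose small-sample behaviour we probe but do not
correct. The limb classifier assumes a walking gait with track-up and a
forelimbs-first landing; other gaits (trot, pace) or sideways landings will
misclassify. The container format stores sparse nonzero sensels only, which
is lossless for simulated data but would discard a real mat's noise floor if
one thresholded before saving.
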