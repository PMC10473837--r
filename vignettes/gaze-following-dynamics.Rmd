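---
title: "Modelling and analysing eye-movement dynamics during dynamic gaze following"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing eye-movement dynamics during dynamic gaze following}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When an observer watches another person (the *gazer*) turn their head to look
at someone, the observer's eyes follow. The oculomotor phenomenology is rich:
first saccades are launched before the gazer's head stops moving and
anticipate the final head direction; on a subset of trials the observer
saccades *back* to the gazer (a reverse, or return, saccade) and then makes a
second, more accurate, forward saccade; and whether a reverse saccade happens
is predictable from the gazer's head kinematics early in the video —
reverse-saccade trials are the ones where the head starts slowly and then
accelerates.

`dynagaze` implements the full analysis chain for this kind of experiment —
saccade detection, forward/reverse classification, gazer head-feature
extraction, event-aligned resampling statistics, and movie-level
predictability — together with a synthetic-trial generator that emulates the
experimental design, so every stage can be exercised and validated without
access to recorded data.

## Data model

All positions are screen-centred Cartesian coordinates in degrees of visual
angle (dva), x rightward, y upward; angles are degrees, counterclockwise
positive. Three streams describe a trial:

* **Eye samples** at 1000 Hz: `t_ms`, `x_deg`, `y_deg`, `valid`.
* **Gazer-vector series** at 30 fps: per frame, the vector from the gazer's
  head (`origin`) to the momentary estimated gazed location (`endpoint`),
  plus a visibility flag for gaze-contingent freezes/erasures. A 1.2 s video
  has 36 frames on the grid t = k/30, k = 0..35 (the frame-timestamp
  convention is a package choice; only relative timing matters downstream).
* **Trial metadata**: condition (`target_present` / `distractor_present` /
  `goal_absent`), the gaze-goal location, the annotated head-stop time, and
  the gaze-contingent manipulation flag.

## Saccade detection

Saccades are detected from the raw samples with the classic
velocity/acceleration criteria: 35 deg/s and 9500 deg/s². Numerical choices
that the thresholds do not fix:

* Position is smoothed with a 5-sample moving average before central
  differencing; acceleration is the derivative of the boxcar-smoothed speed
  over a ±2-sample base. The wider base matters: with per-sample fixational
  jitter of 0.05 dva, a ±1-sample second difference has a noise SD of
  ~4600 deg/s² and crosses the 9500 deg/s² criterion about 4% of the time,
  while the ±2-sample estimator's noise SD is ~960 deg/s² and never crosses
  it. Saccadic accelerations (≥ ~10⁴ deg/s² for amplitudes above 1 dva)
  remain far above threshold.
* An event starts when **either** criterion is exceeded (`logic = "any"`),
  matching the research tracker's online parser; the conjunction is
  available as a switch.
* Runs closer than 20 ms are merged; events shorter than 6 ms or smaller
  than 0.3 dva are discarded; events overlapping invalid samples (blinks)
  are dropped. These three values are not given by the recording criteria;
  they are set to suppress jitter artifacts and are exposed as arguments.

On generator output the detector recovers ≥ 95% of ground-truth events with
a median onset error of 0 ms (see `test-saccade-events.R`).

## Gazer head features

Four per-frame features are computed from the gazer-vector series:

* **distance** — length of the gazer vector;
* **angular displacement** — unsigned angle between the current and the
  initial gazer vector, in [0, 180];
* **velocity** — frame difference of displacement × frame rate, smoothed
  with a normalized 5-frame boxcar. Displacement is unsigned, so the sign is
  assigned by whether the step reduces the angle to the goal direction:
  positive velocity means the head rotates toward the gaze goal. This
  reproduces the negative-velocity epochs seen when a gazer looks away at
  the end of a video.
* **acceleration** — frame difference of velocity × frame rate, same
  smoothing.

The kernel is a normalized boxcar (uniform weights 1/5) — the smoothing
width is specified by the upstream analysis convention, the shape is a
package choice — with edges renormalized over the frames actually available.
Frames where the gazer is frozen out or erased carry missing values and are
excluded from event-aligned averages. Velocity units are deg/s (the frame
difference is scaled by the frame rate before smoothing).

The **head-stop benchmark** is the mean velocity over the 200 ms before each
movie's annotated head stop (consensus of annotators), with a bootstrap 95%
CI of the grand mean across movies; it serves as the "head is about to stop"
reference band in event-aligned figures.

## Forward and reverse saccades

A saccade is *forward* if its direction has positive cosine similarity with
the gazer goal vector (head centroid → goal location), *reverse* if it
follows at least one forward saccade, has negative cosine similarity, and
lands within 2.5 dva of the gazer (a re-fixation); backward saccades landing
farther out are overshoot corrections and are labelled *other*. Three error
measures are computed per saccade: angular (saccade vector vs start→goal
vector), amplitude (|saccade amplitude − start-to-goal distance|), and
Euclidean (endpoint-to-goal distance).

Two quantities need conventions the classification rules do not provide:

* The *first gaze-following saccade* needs a minimum amplitude so that
  microsaccades do not count; we use 1.0 dva, aligned with the 1.5 dva
  fixation-control window of the paradigm.
* The *anticipation lead* — how long after saccade initiation the gazer's
  head direction reaches the saccade's direction — is the earlier of (a) the
  first frame at or after onset whose gazer vector is within 5° of the
  saccade direction and (b) the linearly interpolated moment the rotating
  gazer vector sweeps past the saccade direction (a sign change of the
  signed angular difference); trials where neither occurs are censored. On a
  constant 100 deg/s rotation starting 35° away, rule (a) fires at 0.30 s
  and rule (b) at 0.35 s, so the reported lead is 0.30 s; with the tolerance
  sent to zero the sweep-past rule alone gives 0.35 s. Both cases are frozen
  in tests.

Event-aligned averages resample each trial's 30 fps feature curve onto the
analysis grid with nearest-frame values — no interpolation, so values never
leak across a gaze-contingent freeze/erase boundary — then average within
subject by group and bootstrap a 95% band of the group mean across subjects.
Trials whose first detected saccade is labelled *other* are excluded from
first-saccade analyses and counted in the report.

## Statistical machinery

* **Participant bootstrap**: subjects are resampled with replacement; the
  statistic is the mean paired difference; the two-sided p is
  2·min(P(diff\* ≤ 0), P(diff\* ≥ 0)), floored at 1/n_boot (results beyond
  the floor print as "p < 1e-4" at 10,000 resamples). Cohen's d uses the
  paired convention d_z = mean(d)/sd(d). For n = 3 the `exact` mode
  enumerates all 27 resamples, which the tests compare against a brute-force
  enumeration oracle.
* **Cluster-based sign-flip permutation** for paired curve comparisons:
  pointwise paired t statistics; cluster-forming threshold = two-sided t at
  α = 0.05 with n−1 df; cluster statistic = sum of t (mass); null = max
  |mass| over Monte-Carlo per-subject sign flips; cluster p uses the
  (1 + #{null ≥ obs}) / (n_perm + 1) convention so p ∈ (0, 1]. Calibration
  tests hold the family-wise error at 0.05 ± 0.02 on exchangeable Gaussian
  nulls.
* **BH-FDR** via the standard step-up (delegated to `p.adjust`; the test
  suite checks it against a literal step-up implementation on all small
  lists).
* **2×2 repeated-measures ANOVA** by closed-form SS decomposition, each
  effect tested against its subject-by-effect interaction (F with df
  (1, n−1); partial η² = SS_eff/(SS_eff+SS_err)). The decomposition is
  cross-checked against `aov()` with Error strata; degenerate designs report
  the F = ∞ / F = 0 sentinels. The closed form keeps the 1000-replication
  type-I calibration cheap.
* **Power tools**: a truncated-normal coverage simulation (subject-level
  reverse-saccade proportions ~ N(0.22, 0.11) truncated to [0, 1]; 5-subject
  replicate means; coverage of [11%, 33%] reproduces the planning value of
  ~98%) and a simulated minimum-detectable-difference by bisection over a
  common-random-numbers power curve, which matches the closed-form normal
  approximation (z_{1−α/2}+z_{pow})·(σ/√n_trials)/√n_subjects within 10% at
  study-scale subject counts. The truncated-normal model stands in for
  resampling empirical subject proportions, which would require the original
  records; the MDD model contains trial noise only (no between-subject
  variance component), so its output is a lower bound for a real design.

## Movie predictability

Per-movie reverse-saccade proportions are median-split (strictly above the
median → `high`; ties → `low`, mirroring the strict "greater than" high
definition). For each head feature and each expanding window [0, t_end) the
per-frame values form a movies × frames matrix; a radial-basis SVM with
fixed hyperparameters (cost 1, kernel width 1/n_features — the kernel family
is given, the hyperparameters are package choices) is evaluated
leave-one-movie-out, with per-column z-scoring fitted inside each training
fold to avoid leakage. Raw per-frame values (not window summaries) are the
predictors.

One subtlety documented here because it affects chance baselines: with
labels *permuted* from an exactly balanced vector, leave-one-out accuracy is
structurally below 0.5 (the held-out movie's class is always the training
minority). The chance-level tests therefore draw labels iid, which is the
unbiased baseline.

## The synthetic-trial generator

The generator's defaults are the study conditions; they are set once and the
tests run against them.

* **Design**: each video exists as a goal-person present and absent
  stimulus; per session every stimulus appears once in seeded random order;
  present trials split equally into target and distractor by video family.
  Defaults: 80 videos × 2 versions × 2 sessions = 320 trials per observer
  with a 25/25/50 target/distractor/absent mix (exact when the video count
  is even). Gaze-contingent schemes flag a random 50% of trials (freeze
  after the first forward saccade; erase the gazer on reverse).
* **Head trajectories**: 1.2 s at 30 fps. Goal eccentricity ~ N(6, 3) dva
  truncated to [1.3, 13.6]; random goal direction. Two profiles:
  *smooth-stop* — raised-cosine (minimum-jerk-like) displacement over
  ~0.61 s through a ~70° rotation (early mean velocity ≈ 95 deg/s) — and
  *slow-start-accelerating* — a 55 deg/s plateau for 0.35 s, then an
  accelerating ramp, over ~0.65 s through ~45° (early mean velocity
  55 deg/s). The two early velocities bracket the empirical contrast between
  non-reverse and reverse trials (≈ 94 vs ≈ 64 deg/s). Half the videos get
  the slow profile. 87% of videos add a late look-away (~0.98 s). Per-frame
  gaze-estimation noise: direction SD 2.5° (between the model estimator's
  and human annotators' reported scatter), length SD 0.5 dva. A
  constant-rate profile exists for oracle tests.
* **Observer policy**: the eye starts within the 1.5 dva fixation window on
  the gazer. First-saccade latency is drawn from the fast distribution
  (mean 0.23 s) when the head's mean velocity over the first 0.23 s is below
  70 deg/s, else slow (0.34 s). Direction noise around the goal is larger
  for goal-absent trials (40° vs 20° circular SD); amplitude noise 1.2 dva.
  On slow-start trajectories a reverse saccade is inserted with probability
  0.44 (0.5 × 0.44 = 22% of trials overall, the empirical rate), initiating
  around 0.63 s and landing 0.79 ± 0.28 dva from the gazer; a post-reverse
  forward saccade follows around 0.84 s with its error draws shrunk ×0.6
  (or inflated ×1.6 when the gazer was erased — the causal manipulation).
* **Rendering**: saccades follow the main sequence (duration
  21 ms + 2.2 ms/dva) with a raised-cosine position profile, so every truth
  event clears the detector thresholds (peak velocity A·π/2D, peak
  acceleration A·π²/2D²; amplitudes are floored at 1.1 dva, the smallest
  value whose peak acceleration clears 9500 deg/s²). Fixational jitter is
  iid Gaussian, SD 0.05 dva per sample (the recording noise level is not
  constrained by the paradigm; this is a free parameter).

**What passing tests do and do not show.** The generator reproduces the
*structure* the analyses assume — main-sequence saccades on a quiet
baseline, a deterministic link from slow early head velocity to reverse
saccades, error contrasts by condition — so green tests validate the
analysis chain, the inference calibration, and the end-to-end plumbing. It
does not emulate smooth pursuit, post-saccadic oscillations, blinks (other
than explicit gaps), drift, head-free recording artifacts, or the
gaze-estimation failures of real video models; absolute effect sizes on real
recordings will differ, and detector settings may need retuning for noisier
trackers.

## Problem sizes

Tests and the analysis scripts run at desk scale, chosen so each simulation
still has stable statistics: cohorts of 4–8 subjects × 10–24 videos,
calibration nulls of 500–1000 replications at 200–1000 resamples, and
10,000 resamples where a single run is reported (coverage, bootstrap
contrasts, cluster tests in the analysis scripts).

## Known limitations

* The 25/25/50 condition mix is exact only for an even number of videos.
* Latency in the policy depends on the head profile, not on goal-person
  presence; the empirical latency difference between present and absent
  trials is not built into the generator (its error contrasts are).
* `reverse_stats` treats a trial's reverse-saccade status as binary; trials
  with multiple reverse saccades are counted once in proportions (all events
  appear in the index histogram).
* The pipeline's ANOVA uses video family (target vs distractor) as the
  second factor for absent trials, registering each absent stimulus to its
  paired present video, which is the only consistent 2×2 assignment when
  the goal person is deleted.
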