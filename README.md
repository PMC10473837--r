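# dynagaze

Analysis of observer eye movements while following another person's **dynamic
gaze**: a gazer in a short video turns their head toward a gaze goal, and an
observer's saccades are related, frame by frame, to the gazer's head
kinematics.

The package is aimed at eye-movement researchers working with
gaze-contingent video paradigms. It implements the full analysis chain:

* **Saccade detection** from 1000 Hz eye traces with the classic
  velocity/acceleration criteria (v > 35°/s, a > 9500°/s²), 5-sample
  position smoothing, run merging, and blink handling.
* **Gazer head features** at 30 fps from gazer-vector series: vector
  distance ‖e−o‖, angular displacement ∠(v_t, v_0) ∈ [0°, 180°], signed
  angular velocity (positive toward the goal) and acceleration, each
  smoothed with a normalized 5-frame boxcar; plus the head-stop benchmark
  (mean velocity over the 200 ms before the annotated stop, with a
  bootstrap 95% CI across movies).
* **Forward / reverse classification**: forward ⟺ cos(saccade vector,
  gazer-goal vector) > 0; reverse ⟺ after a forward saccade, cosine < 0 and
  the endpoint within 2.5° of the gazer (re-fixation); overshoot returns are
  "other". Three error measures per saccade — angular, amplitude, Euclidean —
  plus anticipation lead times and event-aligned group averages.
* **Inference**: participant bootstrap (p = 2·min tail proportions, floored
  at 1/n_boot; paired Cohen's d_z), cluster-based sign-flip permutation on
  paired curves (cluster mass = Σt over |t| > t_{α/2,n−1} runs), BH-FDR,
  closed-form 2×2 repeated-measures ANOVA with partial η², a
  truncated-normal coverage simulation, and a simulated minimum detectable
  difference.
* **Movie predictability**: median split of movies by reverse-saccade
  proportion, expanding-window per-frame feature matrices, and
  leave-one-movie-out radial-basis SVM accuracy.
* A **synthetic-trial generator** (`simulate_cohort()`) that emulates the
  paradigm — 1.2 s videos at 30 fps, goal eccentricity ~ N(6°, 3°) truncated
  to [1.3°, 13.6°], main-sequence saccade rendering, slow-start head
  profiles that trigger reverse saccades, gaze-contingent freeze/erase
  manipulations — so the whole chain is testable without recorded data.

See `vignettes/gaze-following-dynamics.Rmd` for the model, conventions and
design choices, and the numbered scripts under `analysis/` for the worked
analysis sequence (simulate → detect → features → classify → inference →
predictability; outputs land in `results/`).

## A worked example

```r
library(dynagaze)

cohort     <- simulate_cohort(n_subjects = 4, n_videos = 12, seed = 7)
events     <- detect_cohort_saccades(cohort)
classified <- classify_cohort(cohort, events)

rs <- reverse_stats(classified)
cat(sprintf("reverse saccades in %.1f%% of trials, mean initiation %.2f s\n",
            100 * rs$overall_proportion, mean(rs$initiation_s)))
#> reverse saccades in 24.0% of trials, mean initiation 0.63 s

rev <- classified[classified$label == "reverse", ]
cat(sprintf("reverse landing distance to gazer: %.2f dva (SD %.2f)\n",
            mean(sqrt(rev$end_x^2 + rev$end_y^2)),
            sd(sqrt(rev$end_x^2 + rev$end_y^2))))
#> reverse landing distance to gazer: 0.83 dva (SD 0.29)

firsts <- subset(classified, is_first_gaze_following & !first_excluded)
firsts$presence <- ifelse(firsts$condition == "goal_absent", "absent", "present")
aggregate(cbind(angular_error, euclidean_error) ~ presence, firsts, mean)
#>   presence angular_error euclidean_error
#> 1   absent          28.1            3.62
#> 2  present          14.2            2.03

cells <- aggregate(euclidean_error ~ subject + presence, firsts, mean)
w <- reshape(cells, idvar = "subject", timevar = "presence", direction = "wide")
bootstrap_test(w$euclidean_error.absent, w$euclidean_error.present,
               n_boot = 10000, seed = 1)
#> Participant bootstrap: mean diff 1.591, 95% CI [1.108, 1.925], p < 0.0001, d = 3.1 (10,000 resamples)
```

Reading the numbers: about a quarter of trials contain a reverse (return)
saccade, initiating around 0.63 s and landing under a degree from the
gazer's head — the observer re-fixates the gazer, then re-launches. First
gaze-following saccades are markedly less accurate when no person is present
at the gaze goal (Euclidean error 3.6° vs 2.0°), and the participant
bootstrap puts that presence effect well past its resolution floor
(p < 1e-4).

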