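# Trial-design composition -------------------------------------------------

test_that("default design yields 160 stimuli, 320 trials and the 25/25/50 mix", {
  des <- generate_design(80, 2, seed = 7)
  expect_equal(nrow(des), 320)
  expect_equal(length(unique(des$stimulus_id)), 160)
  mix <- table(des$condition) / nrow(des)
  expect_equal(unname(mix[["target_present"]]), 0.25)
  expect_equal(unname(mix[["distractor_present"]]), 0.25)
  expect_equal(unname(mix[["goal_absent"]]), 0.5)
})

test_that("every (video, version) pair appears once per session", {
  des <- generate_design(12, 3, seed = 1)
  counts <- table(des$stimulus_id, des$session)
  expect_true(all(counts == 1))
  # single video, single session: one present + one absent trial
  d1 <- generate_design(1, 1, seed = 1)
  expect_equal(nrow(d1), 2)
  expect_setequal(d1$condition, c("target_present", "goal_absent"))
})

test_that("design composition follows the 25/25/50 rule for any even size", {
  for (nv in c(4, 10, 40)) {
    for (ns in c(1, 2)) {
      des <- generate_design(nv, ns, seed = nv + ns)
      expect_equal(sum(des$condition == "goal_absent"), nv * ns)
      expect_equal(sum(des$condition == "target_present"), nv * ns / 2)
      expect_equal(sum(des$condition == "distractor_present"), nv * ns / 2)
    }
  }
})

test_that("manipulation schemes flag exactly half of the trials", {
  des_f <- generate_design(20, 2, manipulation_scheme = "freeze", seed = 3)
  expect_equal(sum(des_f$manipulation == "freeze_after_first_saccade"), 40)
  des_e <- generate_design(20, 2, manipulation_scheme = "erase", seed = 3)
  expect_equal(sum(des_e$manipulation == "erase_gazer_on_reverse"), 40)
})

test_that("invalid design arguments error", {
  expect_error(generate_design(0, 1), "positive")
  expect_error(generate_design(10, -1), "positive")
})

# Head trajectories ----------------------------------------------------------

test_that("1.2 s at 30 fps yields 36 frames on the t = k/30 grid", {
  traj <- generate_head_trajectory(noiseless_params(), seed = 1)
  expect_equal(nrow(traj), 36)
  expect_equal(traj$t_s, (0:35) / 30)
})

test_that("smooth stop ends with the gazer vector on the goal direction", {
  p <- noiseless_params(goal_direction_deg = 30, initial_offset_deg = 60)
  traj <- generate_head_trajectory(p, seed = 1)
  k <- which(traj$t_s >= p$head_move_duration_s)[1] # first frame after the stop
  gv <- c(traj$end_x[k] - traj$origin_x[k],
          traj$end_y[k] - traj$origin_y[k])
  goal_v <- attr(traj, "goal_location") - p$origin_xy
  expect_lt(angle_between(gv, goal_v), 1e-6)
})

test_that("a constant-rate profile is recovered by finite differences", {
  # oracle: displacement at rate r = offset/T means successive frame angles
  # differ by r/fps on interior frames of the movement
  p <- noiseless_params(profile = "constant_rate", initial_offset_deg = 60,
                        head_move_duration_s = 1.0)
  traj <- generate_head_trajectory(p, seed = 1)
  r <- 60 / 1.0
  dirs <- attr(traj, "true_direction_deg")
  moving <- which(traj$t_s > 0 & traj$t_s < 1.0)
  fd <- abs(diff(dirs)) * 30
  expect_true(all(abs(fd[moving[-length(moving)]] - r) < 1e-9))
})

test_that("slow-start profiles are slow early then accelerate", {
  p <- noiseless_params(profile = "slow_start_accelerating",
                        head_move_duration_s = 0.65)
  expect_lt(dynagaze:::trajectory_mean_velocity(p, 0.23), 70)
  ps <- noiseless_params(profile = "smooth_stop")
  expect_gt(dynagaze:::trajectory_mean_velocity(ps, 0.23), 70)
  # accelerates: mean velocity over a late window exceeds the early plateau
  d <- dynagaze:::trajectory_displacement(p, c(0.35, 0.55))
  expect_gt((d[2] - d[1]) / 0.2, p$slow_v0_deg_s)
})

test_that("trajectory parameter validation catches bad inputs", {
  expect_error(head_trajectory_params(goal_eccentricity_deg = -1))
  expect_error(head_trajectory_params(head_move_duration_s = 2, duration_s = 1.2))
})

# Eye traces -----------------------------------------------------------------

test_that("a degenerate noiseless policy yields one forward saccade on the goal", {
  p <- noiseless_params(goal_direction_deg = 45)
  traj <- generate_head_trajectory(p, seed = 2)
  tr <- generate_eye_trace(traj, noiseless_policy(), seed = 3)
  expect_equal(nrow(tr$truth), 1)
  expect_equal(tr$truth$label, "forward")
  expect_equal(c(tr$truth$end_x, tr$truth$end_y),
               unname(attr(traj, "goal_location")), tolerance = 1e-9)
  expect_equal(nrow(tr$eye_samples), 1200)
})

test_that("the same seed reproduces a bit-identical trial", {
  p <- head_trajectory_params(profile = "slow_start_accelerating")
  traj <- generate_head_trajectory(p, seed = 5)
  pol <- observer_policy(p_reverse_given_slow_head = 1)
  t1 <- generate_eye_trace(traj, pol, seed = 11)
  t2 <- generate_eye_trace(traj, pol, seed = 11)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  t3 <- generate_eye_trace(traj, pol, seed = 12)
  expect_false(identical(t1$eye_samples, t3$eye_samples))
})

test_that("rendered saccades satisfy main-sequence kinematic floors", {
  # raised-cosine peak velocity A*pi/(2D) and peak acceleration A*pi^2/(2D^2)
  # must clear the detector thresholds for every truth event
  cohort <- small_cohort()
  truth <- cohort_truth(cohort)
  D <- (truth$offset_ms - truth$onset_ms) / 1000
  peak_v <- truth$amplitude * pi / (2 * D)
  peak_a <- truth$amplitude * pi^2 / (2 * D^2)
  expect_true(all(peak_v > 35))
  expect_true(all(peak_a > 9500))
})

test_that("truth events equal the saccade-shaped segments in the trace", {
  # conservation: with jitter off, samples moving faster than 35 deg/s lie
  # only inside truth event windows, and each event contains such samples
  p <- head_trajectory_params(profile = "slow_start_accelerating")
  traj <- generate_head_trajectory(p, seed = 6)
  pol <- noiseless_policy(p_reverse_given_slow_head = 1)
  tr <- generate_eye_trace(traj, pol, seed = 21)
  expect_equal(nrow(tr$truth), 3)
  v <- sqrt(diff(tr$eye_samples$x_deg)^2 + diff(tr$eye_samples$y_deg)^2) * 1000
  fast <- which(v > 35)
  in_event <- rep(FALSE, length(v))
  for (k in seq_len(nrow(tr$truth))) {
    idx <- (tr$truth$onset_ms[k]):(tr$truth$offset_ms[k])
    in_event[idx] <- TRUE
    expect_true(any(v[idx] > 35))
  }
  expect_true(all(in_event[fast]))
})

test_that("reverse saccades appear only on slow-start trajectories", {
  pol <- observer_policy(p_reverse_given_slow_head = 1)
  smooth <- generate_head_trajectory(noiseless_params(), seed = 1)
  tr_s <- generate_eye_trace(smooth, pol, seed = 2)
  expect_false(any(tr_s$truth$label == "reverse"))
  slow <- generate_head_trajectory(
    noiseless_params(profile = "slow_start_accelerating"), seed = 1
  )
  tr_r <- generate_eye_trace(slow, pol, seed = 2)
  expect_true(any(tr_r$truth$label == "reverse"))
  # reverse lands within the re-fixation radius of the gazer
  rev <- tr_r$truth[tr_r$truth$label == "reverse", ]
  expect_lt(sqrt(rev$end_x^2 + rev$end_y^2), 2.5)
})

# Gaze-contingent manipulations ----------------------------------------------

test_that("freezing holds all gazer vectors at their value at first-saccade onset", {
  p <- head_trajectory_params()
  traj <- generate_head_trajectory(p, seed = 31)
  des <- generate_design(1, 1, seed = 1)[1, ]
  des$manipulation <- "freeze_after_first_saccade"
  tr <- generate_eye_trace(traj, observer_policy(), des, seed = 32)
  frozen <- apply_manipulation(tr)
  t0 <- tr$truth$onset_ms[1] / 1000
  gs <- frozen$gazer_series
  after <- gs$t_s >= t0
  k0 <- max(which(gs$t_s <= t0))
  expect_true(all(gs$end_x[after] == gs$end_x[k0]))
  expect_true(all(gs$end_y[after] == gs$end_y[k0]))
  # head velocity is 0 after the freeze once the smoothing kernel settles
  f <- compute_features(gs, frozen$goal_location)
  settled <- f$t_s > t0 + 3 / 30
  expect_true(all(abs(f$velocity[settled]) < 1e-9, na.rm = TRUE))
})

test_that("manipulation is a no-op without a flag or without a reverse saccade", {
  p <- head_trajectory_params()
  traj <- generate_head_trajectory(p, seed = 41)
  tr <- generate_eye_trace(traj, observer_policy(), seed = 42)
  expect_identical(apply_manipulation(tr), tr)
  des <- tr$design
  des$manipulation <- "erase_gazer_on_reverse"
  tr2 <- tr
  tr2$design <- des
  expect_identical(apply_manipulation(tr2)$gazer_series, tr$gazer_series)
})

test_that("erasing the gazer inflates post-reverse errors", {
  # two-sample simulation: same geometry/policy, erase flag on vs off
  p <- head_trajectory_params(profile = "slow_start_accelerating")
  pol <- observer_policy(p_reverse_given_slow_head = 1)
  des_plain <- generate_design(1, 1, seed = 1)[1, ]
  des_erase <- des_plain
  des_erase$manipulation <- "erase_gazer_on_reverse"
  err_of <- function(des, seeds) {
    vapply(seeds, function(s) {
      traj <- generate_head_trajectory(p, seed = s)
      tr <- generate_eye_trace(traj, pol, des, seed = s + 1000)
      post <- tr$truth[tr$truth$index == 3, ]
      goal <- tr$goal_location
      sqrt((post$end_x - goal[1])^2 + (post$end_y - goal[2])^2)
    }, numeric(1))
  }
  seeds <- 1:60
  e_plain <- err_of(des_plain, seeds)
  e_erase <- err_of(des_erase, seeds)
  expect_gt(mean(e_erase), mean(e_plain))
  expect_true(all(e_erase >= e_plain - 1e-9)) # same draws, scaled factors
})

test_that("gazer frames are marked invisible after an erase-triggered reverse", {
  p <- head_trajectory_params(profile = "slow_start_accelerating")
  traj <- generate_head_trajectory(p, seed = 51)
  des <- generate_design(1, 1, seed = 1)[1, ]
  des$manipulation <- "erase_gazer_on_reverse"
  tr <- apply_manipulation(
    generate_eye_trace(traj, observer_policy(p_reverse_given_slow_head = 1),
                       des, seed = 52)
  )
  t_rev <- tr$truth$onset_ms[tr$truth$label == "reverse"] / 1000
  expect_true(all(!tr$gazer_series$gazer_visible[tr$gazer_series$t_s >= t_rev]))
  expect_true(all(tr$gazer_series$gazer_visible[tr$gazer_series$t_s < t_rev]))
})

# Cohort plumbing ------------------------------------------------------------

test_that("cohort simulation is deterministic and respects its dimensions", {
  c1 <- simulate_cohort(n_subjects = 2, n_videos = 4, n_sessions = 1, seed = 9)
  c2 <- simulate_cohort(n_subjects = 2, n_videos = 4, n_sessions = 1, seed = 9)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_equal(length(c1$trials), 2 * 4 * 2)
  expect_equal(nrow(c1$videos), 4)
  expect_equal(sum(c1$videos$profile == "slow_start_accelerating"), 2)
})

test_that("goal eccentricities respect the truncation bounds", {
  cohort <- small_cohort()
  expect_true(all(cohort$videos$goal_eccentricity_deg >= 1.3))
  expect_true(all(cohort$videos$goal_eccentricity_deg <= 13.6))
})
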