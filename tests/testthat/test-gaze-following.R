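# Classification --------------------------------------------------------------

test_that("forward, reverse and overshoot-return saccades are labelled correctly", {
  gazer <- c(0, 0)
  goal_v <- c(6, 0)
  ev <- dplyr::bind_rows(
    event_row(c(0, 0), c(5, 0), onset_ms = 300, index = 1L),
    event_row(c(5, 0), c(0.5, 0), onset_ms = 600, index = 2L),
    event_row(c(0.5, 0), c(6, 0.2), onset_ms = 900, index = 3L)
  )
  cl <- classify_saccades(ev, goal_v, gazer)
  expect_equal(cl$label, c("forward", "reverse", "forward"))
  expect_true(cl$is_first_gaze_following[1])
  expect_true(cl$is_post_reverse[3])

  # a backward saccade overshooting past the gazer (4 dva away) is "other"
  ev2 <- dplyr::bind_rows(
    event_row(c(0, 0), c(5, 0), onset_ms = 300, index = 1L),
    event_row(c(5, 0), c(-4, 0), onset_ms = 600, index = 2L)
  )
  cl2 <- classify_saccades(ev2, goal_v, gazer)
  expect_equal(cl2$label, c("forward", "other"))
})

test_that("the first saccade of a trial is never labelled reverse", {
  gazer <- c(0, 0)
  # a backward first saccade landing on the gazer still cannot be reverse
  ev <- event_row(c(5, 0), c(0.3, 0), onset_ms = 200, index = 1L)
  cl <- classify_saccades(ev, c(6, 0), gazer)
  expect_equal(cl$label, "other")
})

test_that("every saccade gets exactly one label and labels partition the trial", {
  cohort <- small_cohort()
  events <- detect_cohort_saccades(cohort)
  cl <- classify_cohort(cohort, events)
  expect_true(all(cl$label %in% c("forward", "reverse", "other")))
  firsts <- cl[cl$index == 1, ]
  expect_false(any(firsts$label == "reverse"))
  # classification is deterministic
  cl2 <- classify_cohort(cohort, events)
  expect_identical(cl, cl2)
})

test_that("labels and errors are invariant under rotation and translation", {
  gazer <- c(0, 0)
  goal_v <- c(5, 3)
  ev <- dplyr::bind_rows(
    event_row(c(0.2, -0.1), c(4.5, 3.2), onset_ms = 300, index = 1L),
    event_row(c(4.5, 3.2), c(0.4, 0.3), onset_ms = 650, index = 2L)
  )
  cl0 <- classify_saccades(ev, goal_v, gazer)
  phi <- 123 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  shift <- c(-7, 4)
  tf <- function(p) as.numeric(R %*% p + shift)
  ev_t <- ev
  for (i in 1:2) {
    s <- tf(c(ev$start_x[i], ev$start_y[i]))
    e <- tf(c(ev$end_x[i], ev$end_y[i]))
    ev_t$start_x[i] <- s[1]; ev_t$start_y[i] <- s[2]
    ev_t$end_x[i] <- e[1]; ev_t$end_y[i] <- e[2]
  }
  cl1 <- classify_saccades(ev_t, as.numeric(R %*% goal_v), tf(gazer))
  expect_equal(cl1$label, cl0$label)
  expect_equal(cl1$angular_error, cl0$angular_error, tolerance = 1e-9)
  expect_equal(cl1$amplitude_error, cl0$amplitude_error, tolerance = 1e-9)
  expect_equal(cl1$euclidean_error, cl0$euclidean_error, tolerance = 1e-9)
})

test_that("zero-length saccade vectors are labelled other with a warning", {
  ev <- event_row(c(1, 1), c(1, 1), onset_ms = 300)
  expect_warning(cl <- classify_saccades(ev, c(6, 0), c(0, 0)), "zero-length")
  expect_equal(cl$label, "other")
})

# Error measures ---------------------------------------------------------------

test_that("saccade errors match hand geometry", {
  # endpoint on the goal: all three errors vanish
  e0 <- saccade_errors(event_row(c(0, 0), c(6, 8)), c(6, 8))
  expect_equal(unname(e0), c(0, 0, 0))

  # collinear undershoot: start (0,0), end (3,4), goal (6,8)
  # -> angular 0; amplitude |5 - 10| = 5; euclidean |(3,4)-(6,8)| = 5
  e1 <- saccade_errors(event_row(c(0, 0), c(3, 4)), c(6, 8))
  expect_equal(unname(e1), c(0, 5, 5))

  # orthogonal: start (0,0), end (0,5), goal (5,0)
  # -> angular 90; amplitude 0; euclidean sqrt(50)
  e2 <- saccade_errors(event_row(c(0, 0), c(0, 5)), c(5, 0))
  expect_equal(unname(e2), c(90, 0, sqrt(50)))

  expect_error(saccade_errors(event_row(c(0, 0), c(1, 0)), c(0, 0)), "degenerate")
})

test_that("noiseless first saccades land exactly on the goal (zero euclidean error)", {
  p <- noiseless_params(goal_direction_deg = 120, goal_eccentricity_deg = 7)
  traj <- generate_head_trajectory(p, seed = 1)
  pol <- noiseless_policy()
  tr <- generate_eye_trace(traj, pol, seed = 2)
  err <- saccade_errors(tr$truth[1, ], tr$goal_location)
  expect_equal(unname(err[["euclidean_error"]]), 0, tolerance = 1e-9)
})

# Anticipation lead -------------------------------------------------------------

test_that("anticipation lead is 0 when directions already agree at onset", {
  gs <- make_rotating_series(0, start_dir_deg = 30, goal_dir_deg = 30)
  sacc <- event_row(c(0, 0), 6 * c(cos(pi / 6), sin(pi / 6)), onset_ms = 300)
  expect_equal(anticipation_lead(sacc, gs), 0)
})

test_that("anticipation lead matches the closed form for constant rotation", {
  # gazer rotates at 100 deg/s; saccade points 35 deg ahead at onset (t = 0.3 s).
  # oracle: |angle| = 35 - 100 * (t - 0.3); first frame with |angle| <= 5 is
  # t = 0.6 (angle exactly 5), so lead = 0.30 s; the interpolated sweep-past
  # crossing is at 0.65 s, later, so the tolerance rule wins.
  gs <- make_rotating_series(100, start_dir_deg = 80, goal_dir_deg = -40)
  # at t = 0.3 the gazer points at 80 - 30 = 50 deg; saccade at 15 deg
  sacc <- event_row(c(0, 0), 6 * c(cos(15 * pi / 180), sin(15 * pi / 180)),
                    onset_ms = 300)
  expect_equal(anticipation_lead(sacc, gs, tol_deg = 5), 0.30, tolerance = 1e-9)
  # with a vanishing tolerance only the sweep-past rule fires, at 0.35 s
  expect_equal(anticipation_lead(sacc, gs, tol_deg = 0), 0.35, tolerance = 1e-3)
})

test_that("anticipation lead is censored when the gazer stops short", {
  # gazer rotates from 80 to 30 deg then stops; saccade at 20 deg: 10 deg short
  gs <- make_rotating_series(100, start_dir_deg = 80, goal_dir_deg = 30)
  sacc <- event_row(c(0, 0), 6 * c(cos(20 * pi / 180), sin(20 * pi / 180)),
                    onset_ms = 100)
  expect_true(is.na(anticipation_lead(sacc, gs, tol_deg = 5)))
  expect_error(
    anticipation_lead(event_row(c(0, 0), c(6, 0), onset_ms = 5000), gs),
    "span"
  )
})

# Event-aligned averages ----------------------------------------------------------

test_that("identical constant curves average to the constant with a tight band", {
  grid_t <- (0:35) / 30
  curves <- dplyr::bind_rows(lapply(1:6, function(s) {
    dplyr::bind_rows(lapply(1:3, function(tr) {
      tibble::tibble(
        subject = paste0("s", s), trial_id = paste0("s", s, "_t", tr),
        group = "g", t_s = grid_t, value = 4.2
      )
    }))
  }))
  aligns <- tibble::tibble(trial_id = unique(curves$trial_id), align_s = 0)
  al <- align_and_average(curves, aligns, window = c(0, 1), n_boot = 500, seed = 1)
  expect_true(all(abs(al$group_stats$mean - 4.2) < 1e-12))
  expect_true(all(abs(al$group_stats$hi - al$group_stats$lo) < 1e-12))
})

test_that("alignment registers each trial's event to t = 0 exactly", {
  grid_t <- (0:35) / 30
  offsets <- c(a = 6, b = 12) # alignment at frame 6 and 12
  curves <- dplyr::bind_rows(lapply(names(offsets), function(id) {
    tibble::tibble(
      subject = "s1", trial_id = id, group = "g", t_s = grid_t,
      value = as.numeric(seq_along(grid_t) - 1 == offsets[[id]])
    )
  }))
  aligns <- tibble::tibble(trial_id = names(offsets),
                           align_s = grid_t[offsets + 1])
  al <- align_and_average(curves, aligns, window = c(-0.1, 0.1),
                          n_boot = 100, seed = 1)
  at0 <- al$group_stats$mean[abs(al$group_stats$t_s) < 1e-9]
  expect_equal(at0, 1) # both trials' spikes map onto the grid origin
})

test_that("slow-start reverse trials show lower early group-mean velocity", {
  cohort <- simulate_cohort(
    n_subjects = 5, n_videos = 12, n_sessions = 1,
    policy = observer_policy(p_reverse_given_slow_head = 1), seed = 314
  )
  feats <- cohort_video_features(cohort)
  cl <- classify_cohort(cohort, detect_cohort_saccades(cohort))
  groups <- cl |>
    dplyr::group_by(.data$subject, .data$trial_id, .data$video_id) |>
    dplyr::summarise(group = ifelse(any(.data$label == "reverse"),
                                    "reverse", "no_reverse"), .groups = "drop")
  vel <- dplyr::select(feats, "video_id", "t_s", value = "velocity")
  curves <- dplyr::inner_join(groups, vel, by = "video_id",
                              relationship = "many-to-many")
  aligns <- tibble::tibble(trial_id = unique(curves$trial_id), align_s = 0)
  al <- align_and_average(curves, aligns, window = c(0, 0.3),
                          n_boot = 200, seed = 2)
  early <- al$group_stats[al$group_stats$t_s <= 0.23, ]
  m_rev <- mean(early$mean[early$group == "reverse"])
  m_no <- mean(early$mean[early$group == "no_reverse"])
  expect_lt(m_rev, m_no)
  # the gap reflects the generator's configured early-velocity contrast
  expect_gt(m_no - m_rev, 15)
})

test_that("an empty group errors by name", {
  curves <- tibble::tibble(subject = "s1", trial_id = "t1", group = "g",
                           t_s = (0:35) / 30, value = 1)
  aligns <- tibble::tibble(trial_id = "zzz", align_s = 0)
  expect_error(align_and_average(curves, aligns), "empty group")
})

# Reverse-saccade summaries ---------------------------------------------------------

test_that("reverse summaries are zero without reverse saccades", {
  cl <- tibble::tibble(
    subject = rep("s1", 3), video_id = 1:3, trial_id = paste0("t", 1:3),
    index = 1L, label = "forward", latency_s = 0.3
  )
  rs <- reverse_stats(cl)
  expect_equal(rs$overall_proportion, 0)
  expect_true(all(rs$per_subject$proportion == 0))
  expect_equal(sum(rs$index_counts), 0L)
})

test_that("reverse proportion matches the binomial expectation of the generator", {
  # p_reverse = 0.25 on slow-start videos (50% of videos) -> ~12.5% of trials
  cohort <- simulate_cohort(
    n_subjects = 6, n_videos = 20, n_sessions = 2,
    policy = observer_policy(p_reverse_given_slow_head = 0.25), seed = 99
  )
  truth <- cohort_truth(cohort)
  has_rev <- tapply(truth$label == "reverse", truth$trial_id, any)
  # trials with no events at all still count as no-reverse
  prop <- sum(has_rev) / length(cohort$trials)
  se <- sqrt(0.125 * 0.875 / length(cohort$trials))
  expect_lt(abs(prop - 0.125), 4 * se + 0.01)
})

test_that("a single always-second reverse concentrates the index histogram", {
  cl <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(
      subject = "s1", video_id = i, trial_id = paste0("t", i),
      index = 1:2, label = c("forward", "reverse"), latency_s = c(0.3, 0.63)
    )
  }))
  rs <- reverse_stats(cl)
  expect_equal(unname(rs$index_counts[["2"]]), 5L)
  expect_equal(sum(rs$index_counts), 5L)
  expect_equal(rs$overall_proportion, 1)
})
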