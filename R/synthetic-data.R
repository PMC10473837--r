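# Synthetic trial generation ------------------------------------------------
#
# Emulates the study's trial structure: 1.2 s videos at 30 fps in which a
# gazer rotates their head toward a gaze goal, and an observer at 1000 Hz
# follows the gaze with main-sequence saccades. Reverse (return) saccades are
# contingent on a slow early head velocity, mirroring the empirical trigger.
# Coordinates are screen-centred Cartesian degrees of visual angle (dva),
# x rightward, y upward; angles in degrees, counterclockwise positive.

#' Generate a balanced trial design
#'
#' Builds the per-observer trial table: each video exists as a goal-person
#' present and a goal-person absent stimulus, and every (video, version) pair
#' appears once per session in a seeded random order. Present-version trials
#' split equally into target-present and distractor-present by video family
#' (the first half of the video ids carry the target person), so a default
#' design has the 25/25/50 target/distractor/absent condition mix.
#'
#' @param n_videos Number of distinct videos (>= 1; the mix is exact when even).
#' @param n_sessions Number of sessions per observer (>= 1).
#' @param manipulation_scheme One of `"none"`, `"freeze"` (a random 50% of
#'   trials freeze the gazer after the first forward saccade) or `"erase"`
#'   (a random 50% of trials erase the gazer after a reverse saccade, when one
#'   occurs).
#' @param seed Integer seed for the trial order and manipulation assignment.
#' @return A tibble with one row per trial: `trial_id`, `session`, `video_id`,
#'   `stimulus_id`, `condition` (`target_present` / `distractor_present` /
#'   `goal_absent`), `video_family` (`target` / `distractor`), `manipulation`.
#' @export
generate_design <- function(n_videos, n_sessions,
                            manipulation_scheme = c("none", "freeze", "erase"),
                            seed = 1L) {
  manipulation_scheme <- match.arg(manipulation_scheme)
  if (!is.numeric(n_videos) || n_videos < 1 || n_videos != round(n_videos)) {
    stop("n_videos must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_sessions) || n_sessions < 1 || n_sessions != round(n_sessions)) {
    stop("n_sessions must be a positive integer", call. = FALSE)
  }
  n_videos <- as.integer(n_videos)
  n_sessions <- as.integer(n_sessions)

  family <- ifelse(seq_len(n_videos) <= ceiling(n_videos / 2), "target", "distractor")
  stimuli <- tibble::tibble(
    video_id = rep(seq_len(n_videos), each = 2L),
    goal_person_present = rep(c(TRUE, FALSE), times = n_videos),
    video_family = rep(family, each = 2L)
  )
  stimuli$stimulus_id <- sprintf(
    "v%03d_%s", stimuli$video_id,
    ifelse(stimuli$goal_person_present, "present", "absent")
  )
  stimuli$condition <- ifelse(
    !stimuli$goal_person_present, "goal_absent",
    ifelse(stimuli$video_family == "target", "target_present", "distractor_present")
  )

  seeds <- derive_seeds(seed, n_sessions + 1L)
  rows <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    ord <- with_seed(seeds[s], sample.int(nrow(stimuli)))
    ses <- stimuli[ord, ]
    ses$session <- s
    rows[[s]] <- ses
  }
  design <- dplyr::bind_rows(rows)
  design$trial_id <- sprintf("t%04d", seq_len(nrow(design)))

  design$manipulation <- "none"
  if (manipulation_scheme != "none") {
    flag <- c(freeze = "freeze_after_first_saccade",
              erase = "erase_gazer_on_reverse")[[manipulation_scheme]]
    n <- nrow(design)
    pick <- with_seed(seeds[n_sessions + 1L], sample.int(n, floor(n / 2)))
    design$manipulation[pick] <- flag
  }
  design$seed <- seed
  dplyr::select(
    design, "trial_id", "session", "video_id", "stimulus_id",
    "condition", "video_family", "goal_person_present", "manipulation", "seed"
  )
}

#' Head-trajectory parameters
#'
#' Parameters of a single gazer head movement. The head rotates from an
#' initial direction (`goal_direction_deg + rotation_sign * initial_offset_deg`)
#' to the goal direction over `head_move_duration_s`, following one of three
#' angular displacement profiles:
#' `"smooth_stop"` (raised-cosine, minimum-jerk-like, decelerating to a stop),
#' `"slow_start_accelerating"` (low constant velocity, then an accelerating
#' ramp — the profile that triggers reverse saccades), or `"constant_rate"`.
#'
#' @param duration_s Video duration in seconds (default 1.2).
#' @param frame_rate_hz Frame rate (default 30).
#' @param goal_eccentricity_deg Eccentricity of the gaze goal from the gazer
#'   head, dva (> 0; study mean 6, SD 3, range 1.3-13.6).
#' @param goal_direction_deg Direction of the gazer-goal vector, degrees.
#' @param head_move_duration_s Head movement duration, seconds (study mean 0.61).
#' @param profile Displacement profile (see above).
#' @param initial_offset_deg Initial-to-goal rotation angle, degrees. Defaults
#'   to 70 (smooth_stop / constant_rate) or 45 (slow_start_accelerating),
#'   giving early mean velocities near 95 vs 55 deg/s.
#' @param lookaway_time_s Optional time at which the gazer starts rotating
#'   away from the goal again (NULL = never).
#' @param overshoot_deg Degrees by which the rotation passes the goal (default 0).
#' @param slow_v0_deg_s Plateau velocity of the slow-start profile, deg/s.
#' @param slow_break_s Duration of the slow plateau, seconds.
#' @param angle_noise_sd_deg Per-frame SD of the estimated gaze direction,
#'   degrees (gaze-estimation noise; default 2.5).
#' @param distance_noise_sd_deg Per-frame SD of the estimated gazer-vector
#'   length, dva (default 0.5).
#' @param rotation_sign +1 or -1, side from which the head approaches the goal.
#' @param origin_xy Gazer head position, dva (default the screen centre c(0, 0)).
#' @return An object of class `head_trajectory_params`.
#' @export
head_trajectory_params <- function(duration_s = 1.2,
                                   frame_rate_hz = 30,
                                   goal_eccentricity_deg = 6,
                                   goal_direction_deg = 0,
                                   head_move_duration_s = 0.61,
                                   profile = c("smooth_stop",
                                               "slow_start_accelerating",
                                               "constant_rate"),
                                   initial_offset_deg = NULL,
                                   lookaway_time_s = NULL,
                                   overshoot_deg = 0,
                                   slow_v0_deg_s = 55,
                                   slow_break_s = 0.35,
                                   angle_noise_sd_deg = 2.5,
                                   distance_noise_sd_deg = 0.5,
                                   rotation_sign = 1,
                                   origin_xy = c(0, 0)) {
  profile <- match.arg(profile)
  if (is.null(initial_offset_deg)) {
    initial_offset_deg <- if (profile == "slow_start_accelerating") 45 else 70
  }
  stopifnot(
    duration_s > 0, frame_rate_hz > 0,
    goal_eccentricity_deg > 0,
    head_move_duration_s > 0, head_move_duration_s <= duration_s,
    initial_offset_deg > 0, overshoot_deg >= 0,
    slow_v0_deg_s > 0, slow_break_s > 0,
    angle_noise_sd_deg >= 0, distance_noise_sd_deg >= 0,
    rotation_sign %in% c(-1, 1), length(origin_xy) == 2
  )
  if (!is.null(lookaway_time_s)) {
    stopifnot(lookaway_time_s > head_move_duration_s, lookaway_time_s < duration_s)
  }
  structure(
    list(
      duration_s = duration_s, frame_rate_hz = frame_rate_hz,
      goal_eccentricity_deg = goal_eccentricity_deg,
      goal_direction_deg = goal_direction_deg,
      head_move_duration_s = head_move_duration_s,
      profile = profile, initial_offset_deg = initial_offset_deg,
      lookaway_time_s = lookaway_time_s, overshoot_deg = overshoot_deg,
      slow_v0_deg_s = slow_v0_deg_s, slow_break_s = slow_break_s,
      angle_noise_sd_deg = angle_noise_sd_deg,
      distance_noise_sd_deg = distance_noise_sd_deg,
      rotation_sign = rotation_sign, origin_xy = as.numeric(origin_xy)
    ),
    class = "head_trajectory_params"
  )
}

# noiseless angular displacement (deg from the initial direction) at time t
trajectory_displacement <- function(params, t) {
  total <- params$initial_offset_deg + params$overshoot_deg
  T <- params$head_move_duration_s
  disp <- switch(
    params$profile,
    smooth_stop = total / 2 * (1 - cos(pi * pmin(t, T) / T)),
    constant_rate = total * pmin(t, T) / T,
    slow_start_accelerating = {
      v0 <- params$slow_v0_deg_s
      tb <- min(params$slow_break_s, 0.6 * T)
      if (v0 * tb >= total) {
        # plateau alone covers the rotation: fall back to constant rate
        total * pmin(t, T) / T
      } else {
        tp <- (tb + T) / 2
        h <- tp - tb
        vp <- (total - v0 * tb - h * v0 / 2) / h
        d_at <- function(tt) {
          ifelse(
            tt <= tb, v0 * tt,
            ifelse(
              tt <= tp,
              v0 * tb + v0 * (tt - tb) + (vp - v0) * (tt - tb)^2 / (2 * h),
              v0 * tb + h * (v0 + vp) / 2 + vp * (tt - tp) -
                vp * (tt - tp)^2 / (2 * (T - tp))
            )
          )
        }
        d_at(pmin(t, T))
      }
    }
  )
  if (!is.null(params$lookaway_time_s)) {
    after <- t > params$lookaway_time_s
    if (any(after)) {
      back <- 60 * (t[after] - params$lookaway_time_s) # deg/s look-away rate
      disp[after] <- pmax(disp[after] - pmin(back, 25), 0)
    }
  }
  disp
}

# analytic mean angular velocity over [0, t_end] of the noiseless profile
trajectory_mean_velocity <- function(params, t_end) {
  stopifnot(t_end > 0)
  trajectory_displacement(params, t_end) / t_end
}

#' Generate a gazer-vector series
#'
#' Renders the per-frame gazer vectors of one video: frames at
#' t = 0, 1/fps, ... < duration; the vector direction rotates from the initial
#' direction to the goal direction following the displacement profile, with
#' optional per-frame gaze-estimation noise in direction and length.
#'
#' @param params A [head_trajectory_params()] object.
#' @param seed Integer seed for the estimation noise.
#' @return A tibble of class `gazer_series` with columns `frame`, `t_s`,
#'   `origin_x`, `origin_y`, `end_x`, `end_y`, `gazer_visible`. Attributes
#'   carry the generating `params`, the `goal_location` and `head_stop_time_s`.
#' @export
generate_head_trajectory <- function(params, seed = 1L) {
  stopifnot(inherits(params, "head_trajectory_params"))
  fps <- params$frame_rate_hz
  n <- floor(params$duration_s * fps + 1e-9)
  t_s <- (seq_len(n) - 1) / fps

  disp <- trajectory_displacement(params, t_s)
  dir_deg <- params$goal_direction_deg +
    params$rotation_sign * (params$initial_offset_deg - disp)

  noise <- with_seed(seed, list(
    ang = rnorm(n, 0, params$angle_noise_sd_deg),
    dist = rnorm(n, 0, params$distance_noise_sd_deg)
  ))
  r <- pmax(params$goal_eccentricity_deg + noise$dist, 0.2)
  th <- deg2rad(dir_deg + noise$ang)

  out <- tibble::tibble(
    frame = seq_len(n) - 1L,
    t_s = t_s,
    origin_x = params$origin_xy[1],
    origin_y = params$origin_xy[2],
    end_x = params$origin_xy[1] + r * cos(th),
    end_y = params$origin_xy[2] + r * sin(th),
    gazer_visible = TRUE
  )
  goal <- params$origin_xy +
    params$goal_eccentricity_deg * unit_vec(params$goal_direction_deg)
  structure(
    out,
    class = c("gazer_series", class(out)),
    params = params,
    goal_location = goal,
    head_stop_time_s = params$head_move_duration_s,
    true_direction_deg = dir_deg
  )
}

#' Observer behaviour policy
#'
#' Tunable parameters of the simulated observer. First-saccade latency is
#' drawn from the fast distribution (study mean 0.23 s) when the head's mean
#' velocity over the first 0.23 s of the video is below
#' `slow_head_thresh_deg_s`, else from the slow distribution (0.34 s).
#' Reverse saccades are inserted with probability `p_reverse_given_slow_head`
#' on slow-start trajectories, initiate around `reverse_latency_s` (0.63 s),
#' and land `reverse_landing_mean_deg` (0.79) +/- `reverse_landing_sd_deg`
#' (0.28) dva from the gazer's head. The post-reverse forward saccade draws
#' its direction/amplitude errors shrunk by `post_reverse_error_shrink`,
#' or inflated by `erase_gazer_error_inflate` when the gazer was erased.
#'
#' @param latency_fast_s,latency_slow_s First-saccade latency means (s).
#' @param latency_sd_s Latency SD (s).
#' @param slow_head_thresh_deg_s Early-head-velocity threshold separating the
#'   fast- from the slow-latency regime (deg/s).
#' @param angular_noise_present_deg,angular_noise_absent_deg Circular SD of
#'   the first-saccade direction around the goal direction (deg), by condition.
#' @param amplitude_noise_deg SD of the saccade amplitude error (dva).
#' @param p_reverse_given_slow_head Probability of a reverse saccade on a
#'   slow-start trajectory.
#' @param reverse_latency_s,reverse_latency_sd_s Reverse-saccade initiation
#'   time mean/SD (s).
#' @param reverse_landing_mean_deg,reverse_landing_sd_deg Landing distance of
#'   the reverse saccade from the gazer head (dva).
#' @param post_reverse_latency_s,post_reverse_latency_sd_s Post-reverse
#'   forward-saccade initiation time mean/SD (s).
#' @param post_reverse_error_shrink Multiplicative factor in (0, 1] applied to
#'   post-reverse error draws.
#' @param erase_gazer_error_inflate Factor >= 1 applied instead when the gazer
#'   was erased before the re-fixation.
#' @param fixation_jitter_deg Per-sample fixational jitter SD (dva).
#' @param sample_rate_hz Eye-tracker sampling rate (>= 250; default 1000).
#' @return An object of class `observer_policy`.
#' @export
observer_policy <- function(latency_fast_s = 0.23,
                            latency_slow_s = 0.34,
                            latency_sd_s = 0.04,
                            slow_head_thresh_deg_s = 70,
                            angular_noise_present_deg = 20,
                            angular_noise_absent_deg = 40,
                            amplitude_noise_deg = 1.2,
                            p_reverse_given_slow_head = 0.44,
                            reverse_latency_s = 0.63,
                            reverse_latency_sd_s = 0.05,
                            reverse_landing_mean_deg = 0.79,
                            reverse_landing_sd_deg = 0.28,
                            post_reverse_latency_s = 0.84,
                            post_reverse_latency_sd_s = 0.05,
                            post_reverse_error_shrink = 0.6,
                            erase_gazer_error_inflate = 1.6,
                            fixation_jitter_deg = 0.05,
                            sample_rate_hz = 1000) {
  stopifnot(
    latency_fast_s > 0, latency_slow_s > 0, latency_sd_s >= 0,
    slow_head_thresh_deg_s > 0,
    angular_noise_present_deg >= 0, angular_noise_absent_deg >= 0,
    amplitude_noise_deg >= 0,
    p_reverse_given_slow_head >= 0, p_reverse_given_slow_head <= 1,
    reverse_latency_s > 0, reverse_latency_sd_s >= 0,
    reverse_landing_mean_deg >= 0, reverse_landing_sd_deg >= 0,
    post_reverse_latency_s > 0, post_reverse_latency_sd_s >= 0,
    post_reverse_error_shrink > 0, post_reverse_error_shrink <= 1,
    erase_gazer_error_inflate >= 1,
    fixation_jitter_deg >= 0, sample_rate_hz >= 250
  )
  structure(as.list(environment()), class = "observer_policy")
}

# main-sequence saccade duration in ms for an amplitude in dva
main_sequence_duration_ms <- function(amplitude_deg) {
  21 + 2.2 * amplitude_deg
}

# smallest rendered amplitude whose raised-cosine profile still clears the
# 35 deg/s and 9500 deg/s^2 detector thresholds with margin
MIN_RENDER_AMPLITUDE <- 1.1

#' Generate an observer eye trace for one trial
#'
#' Renders a 1000 Hz (configurable) eye-position series: fixation at the gazer
#' head, a first gaze-following saccade toward the goal with
#' condition-dependent direction/amplitude noise, an optional reverse saccade
#' back to the gazer (slow-start trajectories only, with probability
#' `p_reverse_given_slow_head`), and a post-reverse forward saccade with
#' shrunk (or, under gazer erasure, inflated) errors. Saccades follow the
#' main sequence (duration 21 ms + 2.2 ms/dva) with a raised-cosine position
#' profile, so their peak velocity and acceleration exceed the detector's
#' thresholds. All generated events are logged in the ground-truth table.
#'
#' @param trajectory A `gazer_series` from [generate_head_trajectory()].
#' @param policy An [observer_policy()].
#' @param design A one-row trial design (a row of [generate_design()] output),
#'   or NULL for a plain unmanipulated present-condition trial.
#' @param seed Integer seed.
#' @return An object of class `synthetic_trial`: a list with `design`,
#'   `gazer_series`, `eye_samples` (tibble `t_ms`, `x_deg`, `y_deg`, `valid`),
#'   `truth` (tibble of true events with intended labels), `goal_location`,
#'   `head_stop_time_s`.
#' @export
generate_eye_trace <- function(trajectory, policy, design = NULL, seed = 1L) {
  stopifnot(inherits(trajectory, "gazer_series"), inherits(policy, "observer_policy"))
  params <- attr(trajectory, "params")
  dur <- params$duration_s
  if (max(trajectory$t_s) < dur - 1.5 / params$frame_rate_hz) {
    stop("trajectory does not cover the trial duration", call. = FALSE)
  }
  if (is.null(design)) {
    design <- tibble::tibble(
      trial_id = "t0001", session = 1L, video_id = 1L,
      stimulus_id = "v001_present", condition = "target_present",
      video_family = "target", goal_person_present = TRUE,
      manipulation = "none", seed = seed
    )
  }
  stopifnot(nrow(design) == 1)

  rate <- policy$sample_rate_hz
  n <- round(dur * rate)
  dt_ms <- 1000 / rate
  t_ms <- (seq_len(n) - 1) * dt_ms

  gazer <- params$origin_xy
  goal <- attr(trajectory, "goal_location")
  ang_sd <- if (design$condition == "goal_absent") {
    policy$angular_noise_absent_deg
  } else {
    policy$angular_noise_present_deg
  }

  slow_head <- trajectory_mean_velocity(params, 0.23) < policy$slow_head_thresh_deg_s
  is_slow_profile <- params$profile == "slow_start_accelerating"

  draws <- with_seed(seed, {
    list(
      p0_off = rnorm(2, 0, 0.25),
      lat1 = rtruncnorm(1,
        if (slow_head) policy$latency_fast_s else policy$latency_slow_s,
        policy$latency_sd_s, 0.08, dur - 0.15
      ),
      e_ang = rnorm(3, 0, ang_sd),
      e_amp = rnorm(3, 0, policy$amplitude_noise_deg),
      u_rev = runif(1),
      rev_lat = rtruncnorm(1, policy$reverse_latency_s,
                           policy$reverse_latency_sd_s, 0.2, dur - 0.22),
      rev_dist = rtruncnorm(1, policy$reverse_landing_mean_deg,
                            policy$reverse_landing_sd_deg, 0.05, 2.2),
      rev_dir = runif(1, 0, 360),
      post_lat = rtruncnorm(1, policy$post_reverse_latency_s,
                            policy$post_reverse_latency_sd_s, 0.3, dur - 0.06),
      jitter = rnorm(2 * n, 0, policy$fixation_jitter_deg)
    )
  })

  # start fixation within the 1.5 dva control window around the gazer head
  off <- draws$p0_off
  if (vec_norm(off) > 1.4) off <- off * 1.4 / vec_norm(off)
  p0 <- gazer + off

  saccade_to <- function(from, err_scale, which) {
    v <- goal - from
    ecc <- vec_norm(v)
    dir <- rad2deg(atan2(v[2], v[1])) + draws$e_ang[which] * err_scale
    amp <- max(ecc + draws$e_amp[which] * err_scale, MIN_RENDER_AMPLITUDE)
    from + amp * unit_vec(dir)
  }

  events <- list()
  target1 <- saccade_to(p0, 1, 1L)
  events[[1]] <- list(onset_s = draws$lat1, from = p0, to = target1, label = "forward")

  has_reverse <- is_slow_profile && draws$u_rev < policy$p_reverse_given_slow_head
  if (has_reverse) {
    landing <- gazer + draws$rev_dist * unit_vec(draws$rev_dir)
    if (vec_norm(landing - target1) < MIN_RENDER_AMPLITUDE) {
      # first saccade already ended near the gazer: land on the far side,
      # or drop the return saccade when even that is too short to render
      landing <- gazer - draws$rev_dist * unit_vec(draws$rev_dir)
      if (vec_norm(landing - target1) < MIN_RENDER_AMPLITUDE) has_reverse <- FALSE
    }
  }
  erased <- FALSE
  if (has_reverse) {
    rev_on <- max(draws$rev_lat, draws$lat1 + 0.12)
    events[[2]] <- list(onset_s = rev_on, from = target1, to = landing, label = "reverse")
    erased <- identical(design$manipulation, "erase_gazer_on_reverse")
    scale3 <- if (erased) policy$erase_gazer_error_inflate else policy$post_reverse_error_shrink
    post_on <- max(draws$post_lat, rev_on + 0.1)
    target3 <- saccade_to(landing, scale3, 3L)
    events[[3]] <- list(onset_s = post_on, from = landing, to = target3, label = "forward")
  }

  # render: piecewise fixation + raised-cosine saccade segments
  x <- rep(p0[1], n)
  y <- rep(p0[2], n)
  truth <- vector("list", length(events))
  prev_offset_ms <- -Inf
  for (k in seq_along(events)) {
    ev <- events[[k]]
    amp <- vec_norm(ev$to - ev$from)
    dur_ms <- main_sequence_duration_ms(amp)
    onset_ms <- max(round(ev$onset_s * 1000 / dt_ms) * dt_ms, prev_offset_ms + 50)
    offset_ms <- min(onset_ms + round(dur_ms / dt_ms) * dt_ms, t_ms[n])
    seg <- which(t_ms >= onset_ms & t_ms <= offset_ms)
    tau <- (t_ms[seg] - onset_ms) / (offset_ms - onset_ms)
    frac <- (1 - cos(pi * tau)) / 2
    x[seg] <- ev$from[1] + frac * (ev$to[1] - ev$from[1])
    y[seg] <- ev$from[2] + frac * (ev$to[2] - ev$from[2])
    after <- which(t_ms > offset_ms)
    x[after] <- ev$to[1]
    y[after] <- ev$to[2]
    truth[[k]] <- tibble::tibble(
      index = k, onset_ms = onset_ms, offset_ms = offset_ms,
      start_x = ev$from[1], start_y = ev$from[2],
      end_x = ev$to[1], end_y = ev$to[2],
      amplitude = amp, label = ev$label
    )
    prev_offset_ms <- offset_ms
  }
  x <- x + draws$jitter[seq_len(n)]
  y <- y + draws$jitter[n + seq_len(n)]

  trial <- structure(
    list(
      design = design,
      gazer_series = trajectory,
      eye_samples = tibble::tibble(
        t_ms = t_ms, x_deg = x, y_deg = y, valid = TRUE
      ),
      truth = dplyr::bind_rows(truth),
      goal_location = goal,
      head_stop_time_s = attr(trajectory, "head_stop_time_s"),
      gazer_location = gazer,
      erased = erased
    ),
    class = "synthetic_trial"
  )
  trial
}

#' Apply the gaze-contingent stimulus manipulation to a trial
#'
#' For `freeze_after_first_saccade`, gazer-vector frames at or after the first
#' forward-saccade onset are held at the last pre-onset frame. For
#' `erase_gazer_on_reverse`, frames at or after the reverse-saccade onset are
#' marked not visible (their features are treated as missing downstream); a
#' trial without a reverse saccade is returned unchanged. A trial whose design
#' has `manipulation = "none"` is a no-op.
#'
#' @param trial A `synthetic_trial`.
#' @return The trial with its `gazer_series` edited.
#' @export
apply_manipulation <- function(trial) {
  stopifnot(inherits(trial, "synthetic_trial"))
  manip <- trial$design$manipulation
  if (is.null(manip) || manip == "none") {
    return(trial)
  }
  gs <- trial$gazer_series
  if (manip == "freeze_after_first_saccade") {
    t0 <- trial$truth$onset_ms[trial$truth$label == "forward"][1] / 1000
    if (is.na(t0)) return(trial)
    k0 <- max(which(gs$t_s <= t0), 1L)
    for (col in c("origin_x", "origin_y", "end_x", "end_y")) {
      gs[[col]][gs$t_s >= t0] <- gs[[col]][k0]
    }
  } else if (manip == "erase_gazer_on_reverse") {
    rev <- trial$truth$onset_ms[trial$truth$label == "reverse"]
    if (length(rev) == 0) return(trial)
    gs$gazer_visible[gs$t_s >= rev[1] / 1000] <- FALSE
  } else {
    stop("unknown manipulation: ", manip, call. = FALSE)
  }
  trial$gazer_series <- gs
  trial
}

#' Simulate a full observer cohort
#'
#' Draws a shared video bank (each video gets a goal eccentricity from
#' Normal(6, 3) truncated to \[1.3, 13.6\] dva, a random goal direction, a
#' head-movement duration around 0.61 s (smooth-stop) or 0.65 s (slow-start),
#' and — with probability 0.87 — a late look-away around 0.98 s), then renders
#' every trial of every observer under the supplied policy, applying any
#' gaze-contingent manipulation the design assigns. Half of the videos use the
#' slow-start profile, so with the default policy about 22% of all trials
#' contain a reverse saccade.
#'
#' @param n_subjects,n_videos,n_sessions Cohort dimensions.
#' @param manipulation_scheme Passed to [generate_design()].
#' @param policy An [observer_policy()].
#' @param p_slow_videos Fraction of videos given the slow-start profile.
#' @param seed Integer seed for everything.
#' @return An object of class `gaze_cohort`: list with `videos` (tibble of
#'   video parameters plus a `trajectory` list-column and annotated head-stop
#'   times), `designs` (all subjects' trial tables), `trials` (list of
#'   `synthetic_trial`), `policy`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 5, n_videos = 20, n_sessions = 1,
                            manipulation_scheme = "none",
                            policy = observer_policy(),
                            p_slow_videos = 0.5,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, n_videos >= 1, n_sessions >= 1,
            p_slow_videos >= 0, p_slow_videos <= 1)
  seeds <- derive_seeds(seed, 2L + n_videos + n_subjects)
  video_seeds <- seeds[2L + seq_len(n_videos)]
  subject_seeds <- seeds[2L + n_videos + seq_len(n_subjects)]

  n_slow <- round(p_slow_videos * n_videos)
  vid <- with_seed(seeds[1], {
    slow <- sample(c(rep(TRUE, n_slow), rep(FALSE, n_videos - n_slow)))
    tibble::tibble(
      video_id = seq_len(n_videos),
      profile = ifelse(slow, "slow_start_accelerating", "smooth_stop"),
      goal_eccentricity_deg = rtruncnorm(n_videos, 6, 3, 1.3, 13.6),
      goal_direction_deg = runif(n_videos, 0, 360),
      head_move_duration_s = ifelse(
        slow,
        rtruncnorm(n_videos, 0.65, 0.06, 0.45, 0.95),
        rtruncnorm(n_videos, 0.61, 0.06, 0.40, 0.90)
      ),
      initial_offset_deg = ifelse(
        slow,
        rtruncnorm(n_videos, 45, 6, 30, 60),
        rtruncnorm(n_videos, 70, 8, 50, 90)
      ),
      rotation_sign = sample(c(-1, 1), n_videos, replace = TRUE),
      lookaway = runif(n_videos) < 0.87,
      lookaway_time_s = rtruncnorm(n_videos, 0.98, 0.1, 0.7, 1.15),
      annot_noise = rnorm(n_videos, 0, 0.03 / sqrt(3))
    )
  })
  vid$lookaway_time_s <- pmax(vid$lookaway_time_s, vid$head_move_duration_s + 0.05)
  # consensus of three simulated annotators marking the head stop
  vid$head_stop_annotated_s <- pmin(
    pmax(vid$head_move_duration_s + vid$annot_noise, 0.1),
    1.19
  )
  vid$annot_noise <- NULL

  vid$trajectory <- lapply(seq_len(n_videos), function(i) {
    p <- head_trajectory_params(
      goal_eccentricity_deg = vid$goal_eccentricity_deg[i],
      goal_direction_deg = vid$goal_direction_deg[i],
      head_move_duration_s = vid$head_move_duration_s[i],
      profile = vid$profile[i],
      initial_offset_deg = vid$initial_offset_deg[i],
      lookaway_time_s = if (vid$lookaway[i]) vid$lookaway_time_s[i] else NULL,
      rotation_sign = vid$rotation_sign[i]
    )
    generate_head_trajectory(p, seed = video_seeds[i])
  })

  designs <- vector("list", n_subjects)
  trials <- list()
  for (s in seq_len(n_subjects)) {
    des <- generate_design(n_videos, n_sessions, manipulation_scheme,
                           seed = subject_seeds[s])
    des$subject <- sprintf("s%02d", s)
    des$trial_id <- paste0(des$subject, "_", des$trial_id)
    designs[[s]] <- des
    trial_seeds <- derive_seeds(subject_seeds[s] + 1L, nrow(des))
    for (i in seq_len(nrow(des))) {
      row <- des[i, ]
      tr <- generate_eye_trace(
        vid$trajectory[[row$video_id]], policy, row, seed = trial_seeds[i]
      )
      tr <- apply_manipulation(tr)
      trials[[row$trial_id]] <- tr
    }
  }
  structure(
    list(
      videos = vid,
      designs = dplyr::bind_rows(designs),
      trials = trials,
      policy = policy,
      seed = seed
    ),
    class = "gaze_cohort"
  )
}

#' Tidy accessors for a simulated cohort
#'
#' `cohort_truth()` stacks the ground-truth event logs; `cohort_eye_samples()`
#' stacks the raw eye traces (large); `cohort_gazer_series()` stacks the
#' per-trial (possibly manipulated) gazer-vector series.
#'
#' @param cohort A `gaze_cohort`.
#' @return A tibble keyed by `trial_id`.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dplyr::bind_rows(lapply(names(cohort$trials), function(id) {
    tr <- cohort$trials[[id]]
    if (nrow(tr$truth) == 0) return(NULL)
    dplyr::mutate(tr$truth, trial_id = id, .before = 1)
  }))
}

#' @rdname cohort_truth
#' @export
cohort_eye_samples <- function(cohort) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dplyr::bind_rows(lapply(names(cohort$trials), function(id) {
    dplyr::mutate(cohort$trials[[id]]$eye_samples, trial_id = id, .before = 1)
  }))
}

#' @rdname cohort_truth
#' @export
cohort_gazer_series <- function(cohort) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dplyr::bind_rows(lapply(names(cohort$trials), function(id) {
    gs <- cohort$trials[[id]]$gazer_series
    dplyr::mutate(tibble::as_tibble(gs), trial_id = id, .before = 1)
  }))
}
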