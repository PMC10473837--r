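# Shared fixtures: all synthetic, built in code at test time.

# a policy with every noise source switched off and no reverse saccades
noiseless_policy <- function(...) {
  args <- utils::modifyList(
    list(
      latency_sd_s = 0,
      angular_noise_present_deg = 0, angular_noise_absent_deg = 0,
      amplitude_noise_deg = 0, p_reverse_given_slow_head = 0,
      fixation_jitter_deg = 0
    ),
    list(...)
  )
  do.call(observer_policy, args)
}

noiseless_params <- function(...) {
  head_trajectory_params(angle_noise_sd_deg = 0, distance_noise_sd_deg = 0, ...)
}

# a flat fixation trace with optional rendered raised-cosine saccades
make_trace <- function(n_ms = 1200, start = c(0, 0), jitter_sd = 0,
                       saccades = list(), seed = 1) {
  set.seed(seed)
  t <- 0:(n_ms - 1)
  x <- rep(start[1], n_ms)
  y <- rep(start[2], n_ms)
  for (sc in saccades) {
    from <- c(x[sc$onset_ms + 1], y[sc$onset_ms + 1])
    amp <- sqrt(sum((sc$to - from)^2))
    dur <- round(21 + 2.2 * amp)
    seg <- sc$onset_ms:(sc$onset_ms + dur)
    frac <- (1 - cos(pi * (seg - sc$onset_ms) / dur)) / 2
    x[seg + 1] <- from[1] + frac * (sc$to[1] - from[1])
    y[seg + 1] <- from[2] + frac * (sc$to[2] - from[2])
    after <- t > max(seg)
    x[after] <- sc$to[1]
    y[after] <- sc$to[2]
  }
  tibble::tibble(
    t_ms = t,
    x_deg = x + rnorm(n_ms, 0, jitter_sd),
    y_deg = y + rnorm(n_ms, 0, jitter_sd),
    valid = TRUE
  )
}

# a gazer-vector series rotating at a constant rate toward a goal direction,
# built directly (independent of the generator)
make_rotating_series <- function(rate_deg_s, start_dir_deg, goal_dir_deg = 0,
                                 r = 6, fps = 30, duration_s = 1.2) {
  n <- floor(duration_s * fps + 1e-9)
  t <- (0:(n - 1)) / fps
  sgn <- sign(goal_dir_deg - start_dir_deg)
  if (sgn == 0) sgn <- 1
  dirs <- start_dir_deg + sgn * pmin(rate_deg_s * t, abs(goal_dir_deg - start_dir_deg))
  tibble::tibble(
    frame = 0:(n - 1), t_s = t,
    origin_x = 0, origin_y = 0,
    end_x = r * cos(dirs * pi / 180),
    end_y = r * sin(dirs * pi / 180),
    gazer_visible = TRUE
  )
}

# simple saccade-event row builder
event_row <- function(start, end, onset_ms = 300, index = 1L, trial_id = "t1") {
  amp <- sqrt(sum((end - start)^2))
  tibble::tibble(
    trial_id = trial_id, index = index,
    onset_ms = onset_ms, offset_ms = onset_ms + round(21 + 2.2 * amp),
    start_x = start[1], start_y = start[2],
    end_x = end[1], end_y = end[2],
    amplitude = amp, peak_velocity = 300, latency_s = onset_ms / 1000
  )
}

# small deterministic cohort shared by several test files (cached per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        n_subjects = 4, n_videos = 10, n_sessions = 1,
        policy = observer_policy(), seed = 42
      )
    }
    cache
  }
})
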