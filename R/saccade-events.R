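# Saccade event detection ---------------------------------------------------
#
# Velocity/acceleration threshold detection on 1000 Hz eye samples, after a
# 5-sample moving-average position smoothing. Thresholds follow the study's
# recording criteria (35 deg/s, 9500 deg/s^2); by default an event starts when
# either threshold is exceeded, matching the research eye tracker's online
# parser (the conjunction is available via `logic = "all"`).

#' Per-sample eye kinematics
#'
#' Smooths x/y with a 5-sample moving average, then estimates speed as the
#' magnitude of the central-difference position derivative and acceleration
#' as the derivative of the (boxcar-smoothed) speed over a +/-2-sample base —
#' the wider base keeps fixational jitter from crossing the 9500 deg/s^2
#' criterion while saccadic accelerations still exceed it by a wide margin.
#' Edge samples carry one-sided estimates; invalid samples propagate as NA
#' gaps.
#'
#' @param samples A data frame with columns `t_ms` (strictly increasing),
#'   `x_deg`, `y_deg` and optionally `valid` (logical).
#' @param smooth_k Width of the position-smoothing boxcar (odd; default 5).
#' @return The input with added columns `speed` (deg/s) and `accel` (deg/s^2).
#' @export
compute_eye_kinematics <- function(samples, smooth_k = 5) {
  stopifnot(all(c("t_ms", "x_deg", "y_deg") %in% names(samples)))
  n <- nrow(samples)
  if (n < 3) stop("insufficient data: need at least 3 samples", call. = FALSE)
  t <- samples$t_ms
  if (any(diff(t) <= 0)) stop("t_ms must be strictly increasing", call. = FALSE)
  valid <- if ("valid" %in% names(samples)) samples$valid else rep(TRUE, n)
  if (sum(valid) < 3) stop("insufficient data: need at least 3 valid samples", call. = FALSE)

  x <- ifelse(valid, samples$x_deg, NA_real_)
  y <- ifelse(valid, samples$y_deg, NA_real_)
  xs <- smooth_boxcar(x, smooth_k)
  ys <- smooth_boxcar(y, smooth_k)

  d_central <- function(p) {
    d <- rep(NA_real_, n)
    d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    d[1] <- (p[2] - p[1]) / (t[2] - t[1])
    d[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    d * 1000 # deg/ms -> deg/s
  }
  vx <- d_central(xs)
  vy <- d_central(ys)
  speed <- sqrt(vx^2 + vy^2)

  sp_s <- smooth_boxcar(speed, smooth_k)
  acc <- rep(NA_real_, n)
  if (n >= 5) {
    acc[3:(n - 2)] <- (sp_s[5:n] - sp_s[1:(n - 4)]) / (t[5:n] - t[1:(n - 4)]) * 1000
  }
  acc[c(1, 2)] <- (sp_s[c(2, 3)] - sp_s[c(1, 2)]) / (t[c(2, 3)] - t[c(1, 2)]) * 1000
  acc[c(n - 1, n)] <- (sp_s[c(n - 1, n)] - sp_s[c(n - 2, n - 1)]) /
    (t[c(n - 1, n)] - t[c(n - 2, n - 1)]) * 1000

  out <- tibble::as_tibble(samples)
  out$speed <- speed
  out$accel <- acc
  out
}

#' Detect saccades in an eye-sample series
#'
#' Contiguous runs of samples exceeding the velocity and/or acceleration
#' thresholds become candidate events; runs separated by less than
#' `merge_gap_ms` are merged; events shorter than `min_duration_ms`, smaller
#' than `min_amplitude_deg`, or overlapping invalid samples are discarded.
#'
#' @param samples Eye samples (see [compute_eye_kinematics()]).
#' @param velocity_thresh Speed threshold, deg/s (default 35).
#' @param accel_thresh Acceleration threshold, deg/s^2 (default 9500).
#' @param logic `"any"` (default; event where speed OR |accel| exceeds its
#'   threshold, the tracker's convention) or `"all"` (conjunction).
#' @param min_duration_ms Minimum event duration (default 6).
#' @param merge_gap_ms Runs closer than this are merged (default 20).
#' @param min_amplitude_deg Minimum start-to-end amplitude (default 0.3).
#' @param trial_id Optional id stored on the events.
#' @return A tibble of saccade events: `trial_id`, `index`, `onset_ms`,
#'   `offset_ms`, `start_x`, `start_y`, `end_x`, `end_y`, `amplitude`,
#'   `peak_velocity`, `latency_s`.
#' @export
detect_saccades <- function(samples,
                            velocity_thresh = 35,
                            accel_thresh = 9500,
                            logic = c("any", "all"),
                            min_duration_ms = 6,
                            merge_gap_ms = 20,
                            min_amplitude_deg = 0.3,
                            trial_id = NULL) {
  logic <- match.arg(logic)
  if (velocity_thresh <= 0 || accel_thresh <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  kin <- if (all(c("speed", "accel") %in% names(samples))) {
    samples
  } else {
    compute_eye_kinematics(samples)
  }
  n <- nrow(kin)
  t <- kin$t_ms
  valid <- if ("valid" %in% names(kin)) kin$valid else rep(TRUE, n)

  over_v <- !is.na(kin$speed) & kin$speed > velocity_thresh
  over_a <- !is.na(kin$accel) & abs(kin$accel) > accel_thresh
  over <- if (logic == "any") over_v | over_a else over_v & over_a
  over[is.na(over)] <- FALSE

  empty <- tibble::tibble(
    trial_id = character(), index = integer(),
    onset_ms = numeric(), offset_ms = numeric(),
    start_x = numeric(), start_y = numeric(),
    end_x = numeric(), end_y = numeric(),
    amplitude = numeric(), peak_velocity = numeric(), latency_s = numeric()
  )
  if (!any(over)) return(empty)

  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  # merge runs separated by a short gap
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- t[runs$start[i]] - t[merged$end[nrow(merged)]]
      if (gap < merge_gap_ms) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }

  ev <- lapply(seq_len(nrow(merged)), function(i) {
    s <- merged$start[i]
    e <- merged$end[i]
    if (t[e] - t[s] < min_duration_ms) return(NULL)
    if (any(!valid[s:e])) return(NULL) # overlaps a blink/gap
    amp <- sqrt((kin$x_deg[e] - kin$x_deg[s])^2 + (kin$y_deg[e] - kin$y_deg[s])^2)
    if (amp < min_amplitude_deg) return(NULL)
    tibble::tibble(
      onset_ms = t[s], offset_ms = t[e],
      start_x = kin$x_deg[s], start_y = kin$y_deg[s],
      end_x = kin$x_deg[e], end_y = kin$y_deg[e],
      amplitude = amp,
      peak_velocity = max(kin$speed[s:e], na.rm = TRUE),
      latency_s = t[s] / 1000
    )
  })
  ev <- dplyr::bind_rows(ev)
  if (nrow(ev) == 0) return(empty)
  ev$index <- seq_len(nrow(ev))
  ev$trial_id <- if (is.null(trial_id)) {
    if ("trial_id" %in% names(samples)) as.character(samples$trial_id[1]) else NA_character_
  } else {
    as.character(trial_id)
  }
  dplyr::select(
    ev, "trial_id", "index", "onset_ms", "offset_ms",
    "start_x", "start_y", "end_x", "end_y",
    "amplitude", "peak_velocity", "latency_s"
  )
}

#' Detect saccades for every trial of a cohort
#'
#' @param cohort A `gaze_cohort` from [simulate_cohort()].
#' @param ... Passed to [detect_saccades()].
#' @return A tibble of events across trials.
#' @export
detect_cohort_saccades <- function(cohort, ...) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dplyr::bind_rows(lapply(names(cohort$trials), function(id) {
    detect_saccades(cohort$trials[[id]]$eye_samples, trial_id = id, ...)
  }))
}
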