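# Gazer head features -------------------------------------------------------
#
# Per-frame features of the gazer-vector series: vector distance, angular
# displacement from the initial vector, signed angular velocity (positive
# when the head rotates toward the goal) and angular acceleration, both
# smoothed with a normalised 5-frame boxcar, mirroring the study's
# frame-difference + kernel-size-5 convolution.

#' Compute per-frame gazer head features
#'
#' @param series A gazer-vector series: data frame with `t_s`, `origin_x`,
#'   `origin_y`, `end_x`, `end_y` and optionally `gazer_visible`.
#' @param goal The gaze-goal location, length-2 (dva). For goal-absent trials
#'   pass the gazed-person location of the paired present video.
#' @param kernel_frames Smoothing kernel width in frames (odd; default 5).
#' @return A tibble with `frame`, `t_s`, `distance` (dva),
#'   `angular_displacement` (deg, in \[0, 180\]), `velocity` (deg/s, signed),
#'   `acceleration` (deg/s^2). Frames with the gazer not visible (frozen-out /
#'   erased) yield NA features.
#' @export
compute_features <- function(series, goal, kernel_frames = 5) {
  stopifnot(all(c("t_s", "origin_x", "origin_y", "end_x", "end_y") %in% names(series)))
  n <- nrow(series)
  if (n < 6) stop("insufficient data: need at least 6 frames", call. = FALSE)
  stopifnot(length(goal) == 2)
  visible <- if ("gazer_visible" %in% names(series)) series$gazer_visible else rep(TRUE, n)

  dt <- diff(series$t_s)
  if (any(dt <= 0)) stop("frames must be time-ordered", call. = FALSE)
  fps <- 1 / median(dt)

  vx <- series$end_x - series$origin_x
  vy <- series$end_y - series$origin_y
  vx[!visible] <- NA_real_
  vy[!visible] <- NA_real_

  distance <- sqrt(vx^2 + vy^2)
  if (any(distance[visible] == 0, na.rm = TRUE)) {
    stop("undefined angle: gazer vector has zero length on a visible frame",
         call. = FALSE)
  }

  first_vis <- which(visible & !is.na(vx))[1]
  if (is.na(first_vis)) stop("no visible frames", call. = FALSE)
  v0 <- c(vx[first_vis], vy[first_vis])

  ang_of <- function(ax, ay, bx, by) {
    # unsigned angle between per-frame vectors (a) and a fixed vector (b)
    ct <- (ax * bx + ay * by) / (sqrt(ax^2 + ay^2) * sqrt(bx^2 + by^2))
    rad2deg(acos(pmin(1, pmax(-1, ct))))
  }
  displacement <- ang_of(vx, vy, v0[1], v0[2])

  gx <- goal[1] - series$origin_x
  gy <- goal[2] - series$origin_y
  ang_goal <- ang_of(vx, vy, gx, gy)

  # signed step: positive when the rotation step reduces the angle to the goal
  step <- c(NA_real_, abs(diff(displacement)))
  toward <- c(NA_real_, diff(ang_goal) <= 0)
  raw_v <- ifelse(toward, step, -step) * fps
  velocity <- smooth_boxcar(raw_v, kernel_frames)

  raw_a <- c(NA_real_, diff(velocity)) * fps
  acceleration <- smooth_boxcar(raw_a, kernel_frames)

  tibble::tibble(
    frame = if ("frame" %in% names(series)) series$frame else seq_len(n) - 1L,
    t_s = series$t_s,
    distance = distance,
    angular_displacement = displacement,
    velocity = velocity,
    acceleration = acceleration
  )
}

#' Head-stop velocity benchmark
#'
#' Mean head angular velocity over the `window_s` seconds preceding each
#' movie's annotated head stop, with a bootstrap 95% confidence interval of
#' the grand mean across movies. The study uses this band as the
#' "head is about to stop" reference.
#'
#' @param feature_series A list of per-movie feature tibbles (from
#'   [compute_features()]).
#' @param stop_times Numeric vector of per-movie head-stop times (seconds),
#'   the consensus (mean) of the available annotations.
#' @param window_s Window length before the stop (default 0.2).
#' @param n_boot Bootstrap resamples across movies (default 10000).
#' @param seed Integer seed.
#' @return An object of class `head_stop_benchmark`: list with `mean_velocity`,
#'   `ci95`, `per_movie`, `window_s`, `n_boot`, `seed`.
#' @export
head_stop_benchmark <- function(feature_series, stop_times, window_s = 0.2,
                                n_boot = 10000, seed = 1L) {
  stopifnot(is.list(feature_series), length(feature_series) == length(stop_times),
            window_s > 0, n_boot >= 1)
  per_movie <- vapply(seq_along(feature_series), function(i) {
    fs <- feature_series[[i]]
    stop_i <- stop_times[i]
    if (stop_i > max(fs$t_s) + 1e-9 || stop_i < min(fs$t_s)) {
      stop("stop_time outside the series span for movie ", i, call. = FALSE)
    }
    lo <- stop_i - window_s
    if (lo < min(fs$t_s)) {
      warning("window truncated at series start for movie ", i, call. = FALSE)
      lo <- min(fs$t_s)
    }
    in_win <- fs$t_s >= lo - 1e-9 & fs$t_s <= stop_i + 1e-9
    mean(fs$velocity[in_win], na.rm = TRUE)
  }, numeric(1))

  m <- length(per_movie)
  boot_means <- with_seed(seed, {
    idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(per_movie[idx], nrow = n_boot))
  })
  ci <- unname(quantile(boot_means, c(0.025, 0.975)))
  structure(
    list(
      mean_velocity = mean(per_movie),
      ci95 = ci,
      per_movie = per_movie,
      window_s = window_s,
      n_boot = n_boot,
      seed = seed
    ),
    class = "head_stop_benchmark"
  )
}

#' @export
print.head_stop_benchmark <- function(x, ...) {
  cat(sprintf(
    "Head-stop benchmark: mean velocity %.1f deg/s over the final %.0f ms\n  95%% bootstrap CI [%.1f, %.1f] deg/s across %d movies\n",
    x$mean_velocity, x$window_s * 1000, x$ci95[1], x$ci95[2], length(x$per_movie)
  ))
  invisible(x)
}

#' Per-movie features for a cohort's video bank
#'
#' Computes gazer features on each unmanipulated video trajectory of a
#' simulated cohort (one series per movie, shared by all trials of that movie).
#'
#' @param cohort A `gaze_cohort`.
#' @param kernel_frames Passed to [compute_features()].
#' @return A tibble keyed by `video_id` with one row per frame.
#' @export
cohort_video_features <- function(cohort, kernel_frames = 5) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dplyr::bind_rows(lapply(seq_len(nrow(cohort$videos)), function(i) {
    traj <- cohort$videos$trajectory[[i]]
    f <- compute_features(traj, attr(traj, "goal_location"), kernel_frames)
    dplyr::mutate(f, video_id = cohort$videos$video_id[i], .before = 1)
  }))
}
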