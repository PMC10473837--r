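# Forward / reverse saccade classification and error measures ---------------

#' Classify saccades as forward, reverse or other
#'
#' A saccade is *forward* when its direction vector has positive cosine
#' similarity with the gazer goal vector; *reverse* when it occurs after at
#' least one forward saccade, has negative cosine similarity, and its endpoint
#' lies within `reverse_radius_deg` of the gazer's head (a re-fixation of the
#' gazer); backward saccades landing farther away are overshoot returns and
#' are labelled *other*. The three saccade error measures are computed
#' against the goal location (`gazer_location + goal_vector`).
#'
#' @param events A tibble of saccade events (see [detect_saccades()]),
#'   time-ordered within the trial.
#' @param goal_vector Gazer goal vector (from the gazer head centroid to the
#'   goal location), length-2, nonzero.
#' @param gazer_location Gazer head location, length-2 (dva).
#' @param reverse_radius_deg Re-fixation radius (default 2.5 dva).
#' @param min_gaze_amplitude_deg Minimum amplitude for a first saccade to
#'   count as gaze-following (default 1.0 dva; excludes microsaccades).
#' @return The events with added columns `label`, `angular_error`,
#'   `amplitude_error`, `euclidean_error`, `is_first_gaze_following`,
#'   `is_post_reverse`.
#' @export
classify_saccades <- function(events, goal_vector, gazer_location,
                              reverse_radius_deg = 2.5,
                              min_gaze_amplitude_deg = 1.0) {
  stopifnot(length(goal_vector) == 2, length(gazer_location) == 2)
  if (vec_norm(goal_vector) == 0) {
    stop("goal_vector must be nonzero", call. = FALSE)
  }
  n <- nrow(events)
  out <- tibble::as_tibble(events)
  out$label <- rep("other", n)
  out$angular_error <- out$amplitude_error <- out$euclidean_error <- rep(NA_real_, n)
  out$is_first_gaze_following <- out$is_post_reverse <- rep(FALSE, n)
  if (n == 0) return(out)
  if (is.unsorted(out$onset_ms)) stop("events must be time-ordered", call. = FALSE)

  goal_location <- gazer_location + goal_vector
  seen_forward <- FALSE
  seen_reverse <- FALSE
  first_gf_done <- FALSE
  for (i in seq_len(n)) {
    v <- c(out$end_x[i] - out$start_x[i], out$end_y[i] - out$start_y[i])
    if (vec_norm(v) == 0) {
      warning("zero-length saccade vector; labelled 'other'", call. = FALSE)
      next
    }
    cosim <- sum(v * goal_vector) / (vec_norm(v) * vec_norm(goal_vector))
    if (cosim > 0) {
      out$label[i] <- "forward"
      if (!first_gf_done && out$amplitude[i] >= min_gaze_amplitude_deg) {
        out$is_first_gaze_following[i] <- TRUE
        first_gf_done <- TRUE
      }
      if (seen_reverse && !any(out$is_post_reverse)) {
        out$is_post_reverse[i] <- TRUE
      }
      seen_forward <- TRUE
    } else if (seen_forward) {
      d_gazer <- vec_norm(c(out$end_x[i], out$end_y[i]) - gazer_location)
      if (d_gazer <= reverse_radius_deg) {
        out$label[i] <- "reverse"
        seen_reverse <- TRUE
      }
    }
    err <- saccade_errors(out[i, ], goal_location)
    out$angular_error[i] <- err[["angular_error"]]
    out$amplitude_error[i] <- err[["amplitude_error"]]
    out$euclidean_error[i] <- err[["euclidean_error"]]
  }
  out
}

#' Saccade error measures relative to the gaze goal
#'
#' Angular error: unsigned angle between the saccade vector and the vector
#' from the saccade start to the goal. Amplitude error: absolute difference
#' between the saccade amplitude and the start-to-goal distance. Euclidean
#' error: distance from the saccade endpoint to the goal location.
#'
#' @param saccade A one-row saccade event (columns `start_x`, `start_y`,
#'   `end_x`, `end_y`).
#' @param goal_location Gaze-goal location, length-2 (dva).
#' @return Named numeric vector `angular_error` (deg), `amplitude_error`
#'   (dva), `euclidean_error` (dva).
#' @export
saccade_errors <- function(saccade, goal_location) {
  stopifnot(nrow(saccade) == 1, length(goal_location) == 2)
  s <- c(saccade$start_x, saccade$start_y)
  e <- c(saccade$end_x, saccade$end_y)
  v <- e - s
  g <- goal_location - s
  if (vec_norm(g) == 0 || vec_norm(v) == 0) {
    stop("undefined angle: degenerate saccade/goal geometry", call. = FALSE)
  }
  c(
    angular_error = angle_between(v, g),
    amplitude_error = abs(vec_norm(v) - vec_norm(g)),
    euclidean_error = vec_norm(e - goal_location)
  )
}

#' Anticipation lead of the first gaze-following saccade
#'
#' Time after saccade initiation until the gazer's head direction reaches the
#' saccade's direction: the earliest frame at or after onset whose gazer
#' vector is within `tol_deg` of the saccade direction, or the (linearly
#' interpolated) moment the rotating gazer vector sweeps past the saccade
#' direction, whichever comes first. `NA` (censored) when neither occurs
#' before the series ends.
#'
#' @param first_saccade A one-row forward saccade event.
#' @param gazer_series A gazer-vector series tibble.
#' @param tol_deg Angular tolerance (default 5).
#' @return Lead time in seconds, or `NA_real_` if censored.
#' @export
anticipation_lead <- function(first_saccade, gazer_series, tol_deg = 5) {
  stopifnot(nrow(first_saccade) == 1, tol_deg >= 0)
  onset_s <- first_saccade$onset_ms / 1000
  if (onset_s > max(gazer_series$t_s)) {
    stop("saccade onset beyond the gazer series span", call. = FALSE)
  }
  sv <- c(first_saccade$end_x - first_saccade$start_x,
          first_saccade$end_y - first_saccade$start_y)
  if (vec_norm(sv) == 0) stop("zero-length saccade vector", call. = FALSE)

  gs <- gazer_series[gazer_series$t_s >= onset_s - 1e-9, ]
  visible <- if ("gazer_visible" %in% names(gs)) gs$gazer_visible else rep(TRUE, nrow(gs))
  gs <- gs[visible, ]
  if (nrow(gs) == 0) return(NA_real_)

  delta <- vapply(seq_len(nrow(gs)), function(k) {
    gv <- c(gs$end_x[k] - gs$origin_x[k], gs$end_y[k] - gs$origin_y[k])
    signed_angle(gv, sv)
  }, numeric(1))

  t_tol <- gs$t_s[which(abs(delta) <= tol_deg)[1]]

  t_cross <- NA_real_
  if (nrow(gs) >= 2) {
    flips <- which(delta[-1] * delta[-length(delta)] < 0 &
                     abs(diff(delta)) < 180)
    if (length(flips) > 0) {
      k <- flips[1]
      frac <- abs(delta[k]) / (abs(delta[k]) + abs(delta[k + 1]))
      t_cross <- gs$t_s[k] + frac * (gs$t_s[k + 1] - gs$t_s[k])
    }
  }

  candidates <- c(t_tol, t_cross)
  if (all(is.na(candidates))) return(NA_real_)
  min(candidates, na.rm = TRUE) - onset_s
}

#' Event-aligned group-averaged feature curves
#'
#' Registers per-trial head-feature curves to an event time, resamples them
#' onto a common grid with nearest-frame values (no interpolation across a
#' gaze-contingent boundary), averages within subject by group, and
#' bootstraps a 95% band of the group mean across subjects.
#'
#' @param curves A tibble with columns `subject`, `trial_id`, `group`, `t_s`,
#'   `value` (one row per trial frame).
#' @param align_times A tibble `trial_id`, `align_s` giving each trial's
#'   alignment-event time (0 for video-onset alignment).
#' @param window Length-2 window around the event, seconds.
#' @param frame_rate_hz Grid resolution (default 30).
#' @param n_boot Bootstrap resamples of subjects (default 2000).
#' @param seed Integer seed.
#' @return An object of class `aligned_signal`: list with `grid` (seconds,
#'   relative to the event), `subject_curves` (tibble subject, group, and one
#'   row per grid point), `group_stats` (tibble group, t_s, mean, lo, hi),
#'   `n_boot`, `seed`.
#' @export
align_and_average <- function(curves, align_times, window = c(-0.4, 0.4),
                              frame_rate_hz = 30, n_boot = 2000, seed = 1L) {
  stopifnot(all(c("subject", "trial_id", "group", "t_s", "value") %in% names(curves)),
            all(c("trial_id", "align_s") %in% names(align_times)),
            length(window) == 2, window[1] < window[2])
  grid <- seq(window[1], window[2], by = 1 / frame_rate_hz)

  dat <- dplyr::inner_join(curves, align_times, by = "trial_id")
  if (nrow(dat) == 0) stop("empty group: no trials after the join", call. = FALSE)

  per_trial <- dat |>
    dplyr::group_by(.data$subject, .data$group, .data$trial_id) |>
    dplyr::group_map(function(d, key) {
      rel <- d$t_s - d$align_s[1]
      vals <- vapply(grid, function(g) {
        j <- which.min(abs(rel - g))
        if (abs(rel[j] - g) > 1 / frame_rate_hz) NA_real_ else d$value[j]
      }, numeric(1))
      tibble::tibble(
        subject = key$subject, group = key$group, trial_id = key$trial_id,
        t_s = grid, value = vals
      )
    }) |>
    dplyr::bind_rows()

  subject_curves <- per_trial |>
    dplyr::group_by(.data$subject, .data$group, .data$t_s) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")

  groups <- unique(subject_curves$group)
  stats <- lapply(groups, function(g) {
    sc <- subject_curves[subject_curves$group == g, ]
    if (nrow(sc) == 0) stop("empty group: ", g, call. = FALSE)
    subs <- unique(sc$subject)
    mat <- matrix(NA_real_, length(subs), length(grid),
                  dimnames = list(subs, NULL))
    for (s in subs) {
      row <- sc[sc$subject == s, ]
      mat[s, match(row$t_s, grid)] <- row$value
    }
    m <- colMeans(mat, na.rm = TRUE)
    bands <- with_seed(seed, {
      bm <- matrix(NA_real_, n_boot, length(grid))
      for (b in seq_len(n_boot)) {
        pick <- sample.int(length(subs), replace = TRUE)
        bm[b, ] <- colMeans(mat[pick, , drop = FALSE], na.rm = TRUE)
      }
      apply(bm, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    })
    tibble::tibble(
      group = g, t_s = grid, mean = m,
      lo = bands[1, ], hi = bands[2, ]
    )
  })

  structure(
    list(
      grid = grid,
      subject_curves = subject_curves,
      group_stats = dplyr::bind_rows(stats),
      n_boot = n_boot,
      seed = seed
    ),
    class = "aligned_signal"
  )
}

#' Reverse-saccade summaries
#'
#' Per-subject and per-movie proportions of trials containing at least one
#' reverse saccade, the ordinal-index histogram of reverse saccades (2nd,
#' 3rd, ... saccade of the trial) and their initiation times.
#'
#' @param classified A tibble of classified saccades with columns `subject`,
#'   `video_id`, `trial_id`, `index`, `label`, `latency_s`.
#' @return A list with `per_subject`, `per_movie`, `index_counts`,
#'   `initiation_s`, `overall_proportion`.
#' @export
reverse_stats <- function(classified) {
  stopifnot(all(c("subject", "video_id", "trial_id", "index", "label", "latency_s")
                %in% names(classified)))
  trials <- classified |>
    dplyr::group_by(.data$subject, .data$video_id, .data$trial_id) |>
    dplyr::summarise(has_reverse = any(.data$label == "reverse"), .groups = "drop")

  per_subject <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      proportion = mean(.data$has_reverse),
      .groups = "drop"
    )
  per_movie <- trials |>
    dplyr::group_by(.data$video_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      proportion = mean(.data$has_reverse),
      .groups = "drop"
    )
  rev <- classified[classified$label == "reverse", ]
  list(
    per_subject = per_subject,
    per_movie = per_movie,
    index_counts = table(factor(rev$index, levels = 1:10)),
    initiation_s = rev$latency_s,
    overall_proportion = mean(trials$has_reverse)
  )
}

#' Classify every detected saccade of a cohort
#'
#' Joins detected events to their trial's goal geometry and design metadata,
#' classifies and scores them, and returns the tidy long-format table the
#' statistics stage consumes. Trials whose first detected saccade is labelled
#' `other` are flagged (`first_excluded`) for exclusion from first-saccade
#' analyses.
#'
#' @param cohort A `gaze_cohort`.
#' @param events Detected events from [detect_cohort_saccades()].
#' @param ... Passed to [classify_saccades()].
#' @return A tibble with one row per saccade.
#' @export
classify_cohort <- function(cohort, events, ...) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  out <- lapply(split(events, events$trial_id), function(ev) {
    tr <- cohort$trials[[ev$trial_id[1]]]
    if (is.null(tr)) stop("unknown trial_id: ", ev$trial_id[1], call. = FALSE)
    gv <- tr$goal_location - tr$gazer_location
    cl <- classify_saccades(ev[order(ev$onset_ms), ], gv, tr$gazer_location, ...)
    cl$subject <- tr$design$subject %||% NA_character_
    cl$video_id <- tr$design$video_id
    cl$condition <- tr$design$condition
    cl$video_family <- tr$design$video_family
    cl$manipulation <- tr$design$manipulation
    cl$session <- tr$design$session
    cl$first_excluded <- nrow(cl) > 0 && cl$label[1] == "other"
    cl
  })
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
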