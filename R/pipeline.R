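# Configuration-driven pipeline and plain-text interchange ------------------

#' Write a simulated cohort to plain-text interchange files
#'
#' Eye samples go to `eye_samples.csv` (trial_id, t_ms, x_deg, y_deg, valid),
#' gazer series to `gazer_series.csv` (trial_id, frame, t_s, origin_x,
#' origin_y, end_x, end_y, gazer_visible), and trial metadata plus the
#' ground-truth event log to `trials.json`.
#'
#' @param cohort A `gaze_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gaze_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_eye <- file.path(dir, "eye_samples.csv")
  p_gaze <- file.path(dir, "gazer_series.csv")
  p_meta <- file.path(dir, "trials.json")

  utils::write.csv(cohort_eye_samples(cohort), p_eye, row.names = FALSE)
  utils::write.csv(cohort_gazer_series(cohort), p_gaze, row.names = FALSE)

  meta <- lapply(names(cohort$trials), function(id) {
    tr <- cohort$trials[[id]]
    list(
      design = as.list(tr$design),
      goal_location = tr$goal_location,
      gazer_location = tr$gazer_location,
      head_stop_time_s = tr$head_stop_time_s,
      truth = tr$truth
    )
  })
  names(meta) <- names(cohort$trials)
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(eye = p_eye, gazer = p_gaze, meta = p_meta))
}

#' Read trial collections from interchange files
#'
#' Reads the CSV/JSON dialects written by [write_cohort()], cross-checks the
#' join on `trial_id`, and estimates the gazer frame rate from the
#' timestamps, warning when it disagrees with `expected_fps`.
#'
#' @param dir Directory containing `eye_samples.csv`, `gazer_series.csv`,
#'   `trials.json`.
#' @param expected_fps Nominal gazer frame rate (default 30).
#' @return A list with `eye_samples`, `gazer_series` (tibbles) and `meta`
#'   (named list per trial).
#' @export
read_trials <- function(dir, expected_fps = 30) {
  paths <- file.path(dir, c("eye_samples.csv", "gazer_series.csv", "trials.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input files: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  eye <- tibble::as_tibble(utils::read.csv(paths[1]))
  gaze <- tibble::as_tibble(utils::read.csv(paths[2]))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)

  ids <- list(eye = unique(eye$trial_id), gaze = unique(gaze$trial_id),
              meta = names(meta))
  all_ids <- unique(unlist(ids))
  for (nm in names(ids)) {
    absent <- setdiff(all_ids, ids[[nm]])
    if (length(absent) > 0) {
      stop("join error: trial ids missing from ", nm, ": ",
           paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
  }
  dt <- diff(gaze$t_s[gaze$trial_id == all_ids[1]])
  fps_est <- 1 / median(dt)
  if (abs(fps_est - expected_fps) > 0.5) {
    warning(sprintf("gazer series measured at %.2f fps; expected %g",
                    fps_est, expected_fps), call. = FALSE)
  }
  list(eye_samples = eye, gazer_series = gaze, meta = meta)
}

default_pipeline_config <- function() {
  list(
    simulation = list(
      n_subjects = 6, n_videos = 12, n_sessions = 1,
      manipulation_scheme = "none", p_slow_videos = 0.5,
      policy = list(), seed = 101L
    ),
    detection = list(velocity_thresh = 35, accel_thresh = 9500,
                     logic = "any", min_duration_ms = 6,
                     merge_gap_ms = 20, min_amplitude_deg = 0.3),
    classification = list(reverse_radius_deg = 2.5, min_gaze_amplitude_deg = 1.0),
    stats = list(n_boot = 2000, n_perm = 1000, seed = 202L),
    predictability = list(window_ends = c(0.1, 0.23, 0.4, 0.6),
                          feature = "velocity"),
    output_dir = NULL,
    write_intermediate = TRUE
  )
}

merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop("config error: unknown key '", full, "'", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "policy") {
      if (!is.list(user[[key]])) {
        stop("config error: '", full, "' must be a block", call. = FALSE)
      }
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates simulate -> detect -> features -> classify -> statistics ->
#' predictability and returns a machine-readable report. The configuration is
#' a nested list (or the path to a YAML/JSON file) with blocks `simulation`,
#' `detection`, `classification`, `stats`, `predictability`, plus
#' `output_dir` and `write_intermediate`; unknown keys are rejected. With an
#' output directory the stage artifacts (events, classified saccades,
#' predictability curve as CSV; report as JSON) are written there.
#'
#' @param config Nested list, or a path to a YAML or JSON config file, or
#'   NULL for the default desk-scale scenario.
#' @return An object of class `analysis_report` (a nested list; see the
#'   `report.json` it writes).
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- merge_config(config %||% list(), default_pipeline_config())

  sim <- cfg$simulation
  policy <- do.call(observer_policy, sim$policy %||% list())
  cohort <- simulate_cohort(
    n_subjects = sim$n_subjects, n_videos = sim$n_videos,
    n_sessions = sim$n_sessions,
    manipulation_scheme = sim$manipulation_scheme,
    policy = policy, p_slow_videos = sim$p_slow_videos, seed = sim$seed
  )

  det <- cfg$detection
  events <- detect_cohort_saccades(
    cohort,
    velocity_thresh = det$velocity_thresh, accel_thresh = det$accel_thresh,
    logic = det$logic, min_duration_ms = det$min_duration_ms,
    merge_gap_ms = det$merge_gap_ms, min_amplitude_deg = det$min_amplitude_deg
  )

  classified <- classify_cohort(
    cohort, events,
    reverse_radius_deg = cfg$classification$reverse_radius_deg,
    min_gaze_amplitude_deg = cfg$classification$min_gaze_amplitude_deg
  )

  features <- cohort_video_features(cohort)
  stop_bench <- head_stop_benchmark(
    split(features, features$video_id),
    cohort$videos$head_stop_annotated_s,
    n_boot = cfg$stats$n_boot, seed = cfg$stats$seed
  )

  firsts <- classified[classified$is_first_gaze_following & !classified$first_excluded, ]
  err_by_cond <- firsts |>
    dplyr::mutate(presence = ifelse(.data$condition == "goal_absent",
                                    "absent", "present")) |>
    dplyr::group_by(.data$subject, .data$presence) |>
    dplyr::summarise(
      angular_error = mean(.data$angular_error),
      amplitude_error = mean(.data$amplitude_error),
      euclidean_error = mean(.data$euclidean_error),
      latency_s = mean(.data$latency_s),
      n = dplyr::n(), .groups = "drop"
    )

  boot_euclid <- NULL
  cells <- tidyr_pivot(err_by_cond, "euclidean_error")
  if (!is.null(cells)) {
    boot_euclid <- bootstrap_test(cells$absent, cells$present,
                                  n_boot = cfg$stats$n_boot,
                                  seed = cfg$stats$seed)
  }

  anova_euclid <- NULL
  cells4 <- firsts |>
    dplyr::mutate(presence = ifelse(.data$condition == "goal_absent",
                                    "absent", "present")) |>
    dplyr::group_by(.data$subject, .data$presence, .data$video_family) |>
    dplyr::summarise(value = mean(.data$euclidean_error), .groups = "drop")
  if (nrow(cells4) == 4 * length(unique(cells4$subject)) &&
      length(unique(cells4$subject)) >= 2) {
    anova_euclid <- rm_anova_2x2(cells4, dv = "value", subject = "subject",
                                 factor_a = "presence", factor_b = "video_family")
  }

  rstats <- reverse_stats(classified)

  leads <- vapply(which(classified$is_first_gaze_following &
                          !classified$first_excluded), function(i) {
    id <- classified$trial_id[i]
    anticipation_lead(classified[i, ], cohort$trials[[id]]$gazer_series)
  }, numeric(1))

  aligned <- NULL
  cluster <- NULL
  has_rev <- rstats$per_movie$proportion
  trial_groups <- classified |>
    dplyr::group_by(.data$subject, .data$trial_id) |>
    dplyr::summarise(group = ifelse(any(.data$label == "reverse"),
                                    "reverse", "no_reverse"), .groups = "drop")
  if (length(unique(trial_groups$group)) == 2 && sum(has_rev) > 0) {
    vel <- features |> dplyr::select("video_id", "t_s", value = "velocity")
    curves <- cohort$designs |>
      dplyr::select("subject", "trial_id", "video_id") |>
      dplyr::inner_join(trial_groups, by = c("subject", "trial_id")) |>
      dplyr::inner_join(vel, by = "video_id", relationship = "many-to-many")
    aligned <- align_and_average(
      curves,
      tibble::tibble(trial_id = unique(curves$trial_id), align_s = 0),
      window = c(0, 0.6), n_boot = min(cfg$stats$n_boot, 1000),
      seed = cfg$stats$seed
    )
    sc <- aligned$subject_curves
    both <- intersect(sc$subject[sc$group == "reverse"],
                      sc$subject[sc$group == "no_reverse"])
    if (length(both) >= 3) {
      mat_of <- function(g) {
        d <- sc[sc$group == g & sc$subject %in% both, ]
        m <- matrix(NA_real_, length(both), length(aligned$grid),
                    dimnames = list(both, NULL))
        for (s in both) {
          row <- d[d$subject == s, ]
          m[s, match(row$t_s, aligned$grid)] <- row$value
        }
        m
      }
      m_rev <- mat_of("reverse")
      m_no <- mat_of("no_reverse")
      keep <- stats::complete.cases(t(m_rev)) & stats::complete.cases(t(m_no))
      if (sum(keep) >= 3) {
        cluster <- cluster_permutation(
          m_rev[, keep, drop = FALSE], m_no[, keep, drop = FALSE],
          n_perm = cfg$stats$n_perm, seed = cfg$stats$seed,
          t_grid = aligned$grid[keep]
        )
      }
    }
  }

  pred_curve <- NULL
  if (length(unique(has_rev)) > 1 && nrow(rstats$per_movie) >= 8) {
    labels <- label_movies(
      setNames(rstats$per_movie$proportion, rstats$per_movie$video_id)
    )
    if (min(table(labels$label)) >= 2) {
      pred_curve <- predictability_curve(
        features, labels, window_ends = cfg$predictability$window_ends,
        feature_names = cfg$predictability$feature
      )
    }
  }

  report <- structure(
    list(
      provenance = list(
        package_version = as.character(utils::packageVersion("dynagaze")),
        config = cfg[setdiff(names(cfg), "output_dir")],
        config_hash = rlang::hash(cfg[setdiff(names(cfg), "output_dir")])
      ),
      counts = list(
        n_trials = length(cohort$trials),
        n_events = nrow(events),
        n_classified = nrow(classified),
        n_first_saccade_trials = nrow(firsts),
        n_excluded_first_other = sum(classified$first_excluded &
                                       classified$index == 1)
      ),
      saccade_errors_by_condition = err_by_cond,
      first_saccade_latency = list(
        mean_s = mean(firsts$latency_s),
        by_presence = tapply(err_by_cond$latency_s, err_by_cond$presence, mean)
      ),
      anticipation_lead = list(
        mean_s = mean(leads, na.rm = TRUE),
        censored_fraction = mean(is.na(leads))
      ),
      reverse_saccades = list(
        overall_proportion = rstats$overall_proportion,
        per_subject = rstats$per_subject,
        mean_initiation_s = if (length(rstats$initiation_s) > 0) {
          mean(rstats$initiation_s)
        } else {
          NA_real_
        },
        applicable = rstats$overall_proportion > 0
      ),
      head_stop_benchmark = list(
        mean_velocity = stop_bench$mean_velocity, ci95 = stop_bench$ci95
      ),
      presence_contrast_euclidean = if (is.null(boot_euclid)) NULL else list(
        observed_diff = boot_euclid$observed_diff,
        p_two_sided = boot_euclid$p_two_sided,
        cohens_d = boot_euclid$cohens_d
      ),
      anova_euclidean = if (is.null(anova_euclid)) NULL else
        tibble::as_tibble(anova_euclid),
      velocity_cluster_contrast = if (is.null(cluster)) NULL else
        cluster$clusters,
      predictability = pred_curve
    ),
    class = "analysis_report"
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (isTRUE(cfg$write_intermediate)) {
      write_cohort(cohort, cfg$output_dir)
      utils::write.csv(events, file.path(cfg$output_dir, "events.csv"),
                       row.names = FALSE)
      utils::write.csv(classified, file.path(cfg$output_dir, "classified.csv"),
                       row.names = FALSE)
      if (!is.null(pred_curve)) {
        utils::write.csv(pred_curve,
                         file.path(cfg$output_dir, "predictability.csv"),
                         row.names = FALSE)
      }
    }
    jsonlite::write_json(unclass(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

# minimal wide pivot: subject x presence for one measure; NULL if unbalanced
tidyr_pivot <- function(err_by_cond, col) {
  w <- split(err_by_cond[[col]], err_by_cond$presence)
  if (length(w) != 2 || length(w[[1]]) != length(w[[2]])) return(NULL)
  subs_a <- err_by_cond$subject[err_by_cond$presence == "absent"]
  subs_p <- err_by_cond$subject[err_by_cond$presence == "present"]
  if (!identical(sort(subs_a), sort(subs_p))) return(NULL)
  list(absent = w$absent[order(subs_a)], present = w$present[order(subs_p)])
}
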