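# Movie-level reverse-saccade predictability --------------------------------
#
# Median-splits movies into high/low reverse-saccade groups and asks how well
# each gazer head feature, over an expanding window from video onset,
# predicts the group with a leave-one-movie-out radial-basis SVM.

#' Median-split movies by reverse-saccade proportion
#'
#' Movies with a proportion strictly above the across-movie median are
#' labelled `high`; ties at the median go to `low`, mirroring the strict
#' "> median" definition of the high group.
#'
#' @param proportions Named (or plain) numeric vector of per-movie
#'   reverse-saccade proportions in \[0, 1\] (>= 4 movies).
#' @return An object of class `movie_labels`: tibble `video_id`,
#'   `reverse_proportion`, `label`, with attribute `split_threshold`.
#' @export
label_movies <- function(proportions) {
  stopifnot(length(proportions) >= 4,
            all(proportions >= 0 & proportions <= 1))
  if (length(unique(proportions)) == 1) {
    stop("degenerate split: all proportions are equal", call. = FALSE)
  }
  med <- median(proportions)
  ids <- names(proportions) %||% as.character(seq_along(proportions))
  out <- tibble::tibble(
    video_id = ids,
    reverse_proportion = unname(proportions),
    label = factor(ifelse(proportions > med, "high", "low"),
                   levels = c("low", "high"))
  )
  structure(out, class = c("movie_labels", class(out)),
            split_threshold = med)
}

#' Build expanding-window feature matrices
#'
#' For each window end, extracts the per-frame values of one head feature
#' over \[0, t_end) for every movie, as a movies x frames matrix (columns are
#' returned raw; standardization happens inside the cross-validation folds).
#'
#' @param features A tibble with columns `video_id`, `t_s` and the feature
#'   columns (e.g. the output of [cohort_video_features()]). All movies must
#'   share the frame grid.
#' @param feature_name One of `"distance"`, `"angular_displacement"`,
#'   `"velocity"`, `"acceleration"`.
#' @param window_ends Numeric vector of window end times, seconds.
#' @return A named list of matrices (one per window end), each with attribute
#'   `t_end` and rownames = video ids.
#' @export
build_windows <- function(features, feature_name, window_ends) {
  feature_name <- match.arg(feature_name,
                            c("distance", "angular_displacement",
                              "velocity", "acceleration"))
  stopifnot(all(c("video_id", "t_s", feature_name) %in% names(features)),
            all(window_ends > 0))
  t_all <- sort(unique(features$t_s))
  if (any(window_ends > max(t_all) + median(diff(t_all)) + 1e-9)) {
    stop("window end beyond the video duration", call. = FALSE)
  }
  ids <- unique(features$video_id)
  wide <- matrix(NA_real_, length(ids), length(t_all),
                 dimnames = list(as.character(ids), NULL))
  for (i in seq_along(ids)) {
    rows <- features[features$video_id == ids[i], ]
    wide[i, match(rows$t_s, t_all)] <- rows[[feature_name]]
  }
  out <- lapply(window_ends, function(te) {
    cols <- which(t_all < te - 1e-9)
    if (length(cols) == 0) stop("window contains no frames", call. = FALSE)
    m <- wide[, cols, drop = FALSE]
    attr(m, "t_end") <- te
    attr(m, "feature_name") <- feature_name
    m
  })
  names(out) <- sprintf("%s_%.3fs", feature_name, window_ends)
  out
}

#' Leave-one-movie-out classification accuracy
#'
#' Radial-basis support-vector classification of the high/low reverse-saccade
#' label from a windowed feature matrix, leave-one-movie-out: columns are
#' z-scored with the training fold's mean/SD (constant columns map to 0), the
#' held-out movie is predicted, and the proportion correct is returned.
#' Fixed hyperparameters: unit cost, kernel width = 1 / n features.
#'
#' @param matrix_w A movies x frames matrix from [build_windows()].
#' @param labels A `movie_labels` object (or a factor of the same length).
#' @param cost SVM regularization weight (default 1).
#' @param gamma Kernel width (default `1 / ncol(matrix_w)`).
#' @return Proportion of held-out movies correctly labelled.
#' @export
loo_accuracy <- function(matrix_w, labels, cost = 1, gamma = NULL) {
  X <- as.matrix(matrix_w)
  y <- if (inherits(labels, "movie_labels")) labels$label else as.factor(labels)
  stopifnot(nrow(X) == length(y))
  if (nlevels(droplevels(y)) < 2 || min(table(droplevels(y))) < 2) {
    stop("need at least 2 movies per class", call. = FALSE)
  }
  if (any(is.na(X))) stop("feature matrix contains missing values", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(X)

  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    mu <- colMeans(tr_x)
    sg <- apply(tr_x, 2, sd)
    sg[sg == 0] <- 1
    tr_z <- sweep(sweep(tr_x, 2, mu), 2, sg, "/")
    te_z <- (X[i, ] - mu) / sg
    fit <- e1071::svm(tr_z, y[-i], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    pred <- predict(fit, matrix(te_z, nrow = 1))
    correct[i] <- as.character(pred) == as.character(y[i])
  }
  mean(correct)
}

#' Predictability curve across features and window ends
#'
#' Runs [loo_accuracy()] for every head feature and every expanding window
#' end, reproducing the accuracy-vs-time-range analysis.
#'
#' @param features Per-movie feature tibble (see [build_windows()]).
#' @param labels A `movie_labels` object whose `video_id`s match `features`.
#' @param window_ends Window end times, seconds.
#' @param feature_names Features to evaluate (default all four).
#' @param ... Passed to [loo_accuracy()].
#' @return A tibble `feature`, `window_end_s`, `proportion_correct`.
#' @export
predictability_curve <- function(features, labels,
                                 window_ends = seq(0.1, 0.8, by = 0.1),
                                 feature_names = c("distance",
                                                   "angular_displacement",
                                                   "velocity", "acceleration"),
                                 ...) {
  stopifnot(inherits(labels, "movie_labels"))
  rows <- list()
  for (fn in feature_names) {
    mats <- build_windows(features, fn, window_ends)
    for (m in mats) {
      ids <- rownames(m)
      lab <- labels[match(ids, labels$video_id), ]
      if (any(is.na(lab$label))) stop("labels missing for some movies", call. = FALSE)
      keep <- stats::complete.cases(m)
      pc <- loo_accuracy(m[keep, , drop = FALSE], droplevels(lab$label[keep]), ...)
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = fn, window_end_s = attr(m, "t_end"), proportion_correct = pc
      )
    }
  }
  dplyr::bind_rows(rows)
}
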