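# Resampling and parametric inference ---------------------------------------

#' Participant bootstrap test for a paired condition difference
#'
#' Resamples subjects with replacement, takes the mean paired difference per
#' resample, and reports the two-sided p value
#' `2 * min(P(diff* <= 0), P(diff* >= 0))`, floored at `1/n_boot` (the study
#' reports such results as "p < 1e-4" at 10,000 resamples), a percentile 95%
#' CI, and Cohen's d for paired data (mean difference / SD of differences).
#' With `exact = TRUE` all `n^n` equally likely resamples are enumerated
#' instead of sampled (feasible for very small n), making the p value exact.
#'
#' @param values_a,values_b Paired per-subject means (equal length, n >= 3).
#' @param n_boot Number of Monte-Carlo resamples (default 10000).
#' @param seed Integer seed.
#' @param exact Enumerate all resamples instead of sampling (default FALSE).
#' @return An object of class `bootstrap_test`: list with `observed_diff`,
#'   `p_two_sided`, `p_at_floor` (logical), `ci95`, `cohens_d`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_test <- function(values_a, values_b, n_boot = 10000, seed = 1L,
                           exact = FALSE) {
  stopifnot(length(values_a) == length(values_b))
  n <- length(values_a)
  if (n < 3) stop("insufficient subjects: need n >= 3", call. = FALSE)
  d <- values_a - values_b

  if (exact) {
    if (n^n > 1e6) stop("exact enumeration infeasible for n = ", n, call. = FALSE)
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    boot <- rowMeans(matrix(d[idx], nrow = nrow(idx)))
    n_eff <- nrow(idx)
  } else {
    boot <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
      rowMeans(matrix(d[idx], nrow = n_boot))
    })
    n_eff <- n_boot
  }

  p_lo <- mean(boot <= 0)
  p_hi <- mean(boot >= 0)
  p_raw <- 2 * min(p_lo, p_hi)
  p <- min(max(p_raw, 1 / n_eff), 1)

  sd_d <- sd(d)
  cohens_d <- if (sd_d == 0) 0 else mean(d) / sd_d

  structure(
    list(
      observed_diff = mean(d),
      p_two_sided = p,
      p_at_floor = p_raw < 1 / n_eff,
      ci95 = unname(quantile(boot, c(0.025, 0.975))),
      cohens_d = cohens_d,
      n_boot = n_eff,
      seed = if (exact) NA_integer_ else seed,
      exact = exact
    ),
    class = "bootstrap_test"
  )
}

#' @export
print.bootstrap_test <- function(x, ...) {
  p_str <- if (x$p_at_floor) sprintf("< %g", 1 / x$n_boot) else sprintf("= %.4g", x$p_two_sided)
  cat(sprintf(
    "Participant bootstrap: mean diff %.4g, 95%% CI [%.4g, %.4g], p %s, d = %.3g (%s resamples)\n",
    x$observed_diff, x$ci95[1], x$ci95[2], p_str, x$cohens_d,
    format(x$n_boot, big.mark = ",")
  ))
  invisible(x)
}

#' Cluster-based sign-flip permutation test on paired curves
#'
#' Computes a paired t statistic at every time point of the subject difference
#' curves; contiguous runs where |t| exceeds the two-sided threshold at
#' `alpha_cluster` (df = n - 1) form clusters with mass = sum of t; the null
#' distribution is the maximum |mass| over random per-subject sign flips.
#' Cluster p values use the `(1 + #{null >= observed}) / (n_perm + 1)`
#' convention so they lie in (0, 1].
#'
#' @param curves_a,curves_b Numeric matrices, subjects x time points, paired
#'   by row and sharing the time grid.
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param alpha_cluster Cluster-forming alpha (default 0.05).
#' @param seed Integer seed.
#' @param t_grid Optional time stamps for the columns.
#' @return An object of class `cluster_test`: list with `clusters` (tibble
#'   `start`, `end`, `t_start`, `t_end`, `mass`, `p`), `threshold`, `n_perm`,
#'   `seed`, `t_stats`.
#' @export
cluster_permutation <- function(curves_a, curves_b, n_perm = 10000,
                                alpha_cluster = 0.05, seed = 1L,
                                t_grid = NULL) {
  curves_a <- as.matrix(curves_a)
  curves_b <- as.matrix(curves_b)
  if (!all(dim(curves_a) == dim(curves_b))) {
    stop("grid mismatch: curve matrices must have identical dimensions", call. = FALSE)
  }
  n <- nrow(curves_a)
  nt <- ncol(curves_a)
  stopifnot(n >= 3, nt >= 1)
  if (is.null(t_grid)) t_grid <- seq_len(nt)
  stopifnot(length(t_grid) == nt)

  D <- curves_a - curves_b
  thr <- qt(1 - alpha_cluster / 2, df = n - 1)

  t_of <- function(means, sds) {
    tt <- means / (sds / sqrt(n))
    tt[!is.finite(tt)] <- 0
    tt
  }
  col_sq <- colSums(D^2)
  obs_mean <- colMeans(D)
  obs_sd <- sqrt(pmax(col_sq - n * obs_mean^2, 0) / (n - 1))
  t_obs <- t_of(obs_mean, obs_sd)

  find_clusters <- function(tt) {
    over <- abs(tt) > thr
    if (!any(over)) return(NULL)
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(start = starts[r$values], end = ends[r$values])
  }
  obs_cl <- find_clusters(t_obs)

  # sign-flip null: per-subject sign flips leave sum(d^2) unchanged,
  # so only the flipped means need recomputing
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
    M <- (S %*% D) / n
    vapply(seq_len(n_perm), function(b) {
      m <- M[b, ]
      s <- sqrt(pmax(col_sq - n * m^2, 0) / (n - 1))
      tt <- t_of(m, s)
      cl <- find_clusters(tt)
      if (is.null(cl)) return(0)
      max(abs(vapply(seq_len(nrow(cl)), function(i) {
        sum(tt[cl$start[i]:cl$end[i]])
      }, numeric(1))))
    }, numeric(1))
  })

  clusters <- if (is.null(obs_cl)) {
    tibble::tibble(start = integer(), end = integer(),
                   t_start = numeric(), t_end = numeric(),
                   mass = numeric(), p = numeric())
  } else {
    mass <- vapply(seq_len(nrow(obs_cl)), function(i) {
      sum(t_obs[obs_cl$start[i]:obs_cl$end[i]])
    }, numeric(1))
    tibble::tibble(
      start = obs_cl$start, end = obs_cl$end,
      t_start = t_grid[obs_cl$start], t_end = t_grid[obs_cl$end],
      mass = mass,
      p = vapply(mass, function(m) {
        (1 + sum(null_max >= abs(m))) / (n_perm + 1)
      }, numeric(1))
    )
  }
  structure(
    list(
      clusters = clusters,
      threshold = thr,
      n_perm = n_perm,
      seed = seed,
      t_stats = tibble::tibble(t_s = t_grid, t = t_obs)
    ),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster-based sign-flip permutation (%d permutations, |t| > %.2f):\n",
              x$n_perm, x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone in rank and capped at 1.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in the input order.
#' @export
fdr_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Two-factor repeated-measures ANOVA on a 2x2 within-subject design
#'
#' Closed-form sum-of-squares decomposition for a complete 2x2 within-subject
#' table of subject cell means: each effect is tested against its own
#' subject-by-effect interaction, giving F with df (1, n - 1), and partial
#' eta squared = SS_effect / (SS_effect + SS_error). A zero effect SS reports
#' F = 0; a zero error SS with a nonzero effect reports F = Inf.
#'
#' @param data A data frame of subject cell means.
#' @param dv,subject,factor_a,factor_b Column names (strings).
#' @return An object of class `rm_anova`: tibble with one row per effect
#'   (`A`, `B`, `A:B`): `effect`, `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
rm_anova_2x2 <- function(data, dv = "value", subject = "subject",
                         factor_a = "A", factor_b = "B") {
  stopifnot(all(c(dv, subject, factor_a, factor_b) %in% names(data)))
  a_lev <- sort(unique(as.character(data[[factor_a]])))
  b_lev <- sort(unique(as.character(data[[factor_b]])))
  subs <- unique(as.character(data[[subject]]))
  n <- length(subs)
  if (length(a_lev) != 2 || length(b_lev) != 2) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)

  # Y[i, j, k]: subject i, level j of A, level k of B
  Y <- array(NA_real_, dim = c(n, 2, 2))
  for (r in seq_len(nrow(data))) {
    i <- match(as.character(data[[subject]][r]), subs)
    j <- match(as.character(data[[factor_a]][r]), a_lev)
    k <- match(as.character(data[[factor_b]][r]), b_lev)
    Y[i, j, k] <- data[[dv]][r]
  }
  if (any(is.na(Y))) {
    stop("incomplete design: every subject needs all 4 cells", call. = FALSE)
  }

  m <- mean(Y)
  m_i <- apply(Y, 1, mean)
  m_j <- apply(Y, 2, mean)
  m_k <- apply(Y, 3, mean)
  m_ij <- apply(Y, c(1, 2), mean)
  m_ik <- apply(Y, c(1, 3), mean)
  m_jk <- apply(Y, c(2, 3), mean)

  ss_a <- n * 2 * sum((m_j - m)^2)
  ss_b <- n * 2 * sum((m_k - m)^2)
  ss_ab <- n * sum((m_jk - outer(m_j, rep(1, 2)) - outer(rep(1, 2), m_k) + m)^2)
  ss_as <- 2 * sum((m_ij - outer(m_i, rep(1, 2)) -
                      outer(rep(1, n), m_j) + m)^2)
  ss_bs <- 2 * sum((m_ik - outer(m_i, rep(1, 2)) -
                      outer(rep(1, n), m_k) + m)^2)
  resid <- Y
  for (i in seq_len(n)) {
    for (j in 1:2) {
      for (k in 1:2) {
        resid[i, j, k] <- Y[i, j, k] - m_ij[i, j] - m_ik[i, k] - m_jk[j, k] +
          m_i[i] + m_j[j] + m_k[k] - m
      }
    }
  }
  ss_abs <- sum(resid^2)

  f_of <- function(ss_eff, ss_err) {
    ms_eff <- ss_eff / 1
    ms_err <- ss_err / (n - 1)
    if (ss_eff <= 1e-12) return(0)
    if (ms_err <= 1e-12) return(Inf)
    ms_eff / ms_err
  }
  eff <- tibble::tibble(
    effect = c("A", "B", "A:B"),
    F = c(f_of(ss_a, ss_as), f_of(ss_b, ss_bs), f_of(ss_ab, ss_abs)),
    df1 = 1L,
    df2 = n - 1L
  )
  eff$p <- ifelse(is.infinite(eff$F), 0,
                  ifelse(eff$F == 0, 1, pf(eff$F, 1, n - 1, lower.tail = FALSE)))
  ss_eff <- c(ss_a, ss_b, ss_ab)
  ss_err <- c(ss_as, ss_bs, ss_abs)
  eff$partial_eta_sq <- ifelse(ss_eff + ss_err <= 1e-12, 0,
                               ss_eff / (ss_eff + ss_err))
  structure(eff, class = c("rm_anova", class(eff)))
}

#' Bootstrap coverage of the small-sample reverse-saccade proportion
#'
#' Planning simulation for a 5-subject replication: subject-level
#' reverse-saccade proportions follow a normal distribution (study mean 22%,
#' SD 11%) truncated to \[0, 1\]; each replicate draws `n_subjects` subjects
#' and takes their mean; coverage is the fraction of replicate means falling
#' inside `interval`.
#'
#' @param mean_prop,sd_prop Mean and SD of the subject-level proportion.
#' @param n_subjects Subjects per replicate (default 5).
#' @param interval Length-2 coverage interval (default c(0.11, 0.33)).
#' @param n_boot Number of replicates (default 10000).
#' @param seed Integer seed.
#' @return Coverage proportion in \[0, 1\].
#' @export
coverage_simulation <- function(mean_prop = 0.22, sd_prop = 0.11,
                                n_subjects = 5, interval = c(0.11, 0.33),
                                n_boot = 10000, seed = 1L) {
  stopifnot(sd_prop >= 0, length(interval) == 2)
  if (interval[1] >= interval[2]) stop("invalid interval", call. = FALSE)
  means <- with_seed(seed, {
    draws <- rtruncnorm(n_boot * n_subjects, mean_prop, sd_prop, 0, 1)
    rowMeans(matrix(draws, nrow = n_boot))
  })
  mean(means >= interval[1] & means <= interval[2])
}

#' Minimum detectable difference by simulation
#'
#' Smallest mean shift for which a paired t test at level `alpha` reaches
#' `target_power`, when each subject's mean is estimated from `n_trials`
#' noisy trials (SD `within_subject_sd`). Found by bisection over a
#' simulated power curve with common random numbers, so the curve is
#' monotone in the shift.
#'
#' @param within_subject_sd Within-subject trial SD, dva.
#' @param n_subjects,n_trials Design size.
#' @param alpha Test level (default 0.05).
#' @param target_power Power to reach (default 0.8).
#' @param n_sim Simulations per power evaluation (default 2000).
#' @param seed Integer seed.
#' @param tol Bisection tolerance on the shift (default 1e-4).
#' @return The minimum detectable difference, dva.
#' @export
min_detectable_difference <- function(within_subject_sd, n_subjects, n_trials,
                                      alpha = 0.05, target_power = 0.8,
                                      n_sim = 2000, seed = 1L, tol = 1e-4) {
  stopifnot(within_subject_sd > 0, n_subjects >= 2, n_trials >= 1,
            alpha > 0, alpha < 1, target_power > 0, target_power < 1)
  se_subj <- within_subject_sd / sqrt(n_trials)
  E <- with_seed(seed, matrix(rnorm(n_sim * n_subjects, 0, se_subj), nrow = n_sim))
  crit <- qt(1 - alpha / 2, df = n_subjects - 1)
  power_at <- function(delta) {
    M <- E + delta
    mu <- rowMeans(M)
    s <- sqrt(rowSums((M - mu)^2) / (n_subjects - 1))
    mean(abs(mu / (s / sqrt(n_subjects))) > crit)
  }
  lo <- 0
  hi <- 4 * se_subj / sqrt(n_subjects) * (qnorm(1 - alpha / 2) + qnorm(target_power))
  it <- 0
  while (power_at(hi) < target_power) {
    hi <- hi * 2
    it <- it + 1
    if (it > 30) stop("bisection failed to bracket the target power", call. = FALSE)
  }
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (power_at(mid) >= target_power) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  hi
}
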