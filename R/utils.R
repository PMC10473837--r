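#' @keywords internal
"_PACKAGE"

#' @importFrom stats filter pnorm qnorm runif rnorm quantile pf qt pt sd
#'   aggregate setNames median p.adjust predict complete.cases
#' @importFrom utils head tail
#' @importFrom rlang .data hash
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# unit vector for a direction given in degrees (counterclockwise from +x)
unit_vec <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  c(cos(th), sin(th))
}

vec_norm <- function(v) sqrt(sum(v^2))

#' Unsigned angle between two 2-D vectors
#'
#' Returns the unsigned angle, in degrees within \[0, 180\], between two
#' screen-space vectors. This is the primitive behind the gazer angular
#' displacement and the saccade angular error.
#'
#' @param v1,v2 Numeric length-2 vectors (x, y), in degrees of visual angle.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' angle_between(c(1, 0), c(0, 1)) # 90
#' @export
angle_between <- function(v1, v2) {
  stopifnot(length(v1) == 2, length(v2) == 2)
  n1 <- vec_norm(v1)
  n2 <- vec_norm(v2)
  if (n1 == 0 || n2 == 0) {
    stop("undefined angle: zero-length vector", call. = FALSE)
  }
  ct <- sum(v1 * v2) / (n1 * n2)
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

# signed angle (degrees, (-180, 180]) rotating `from` onto `to`
signed_angle <- function(from, to) {
  rad2deg(atan2(from[1] * to[2] - from[2] * to[1], sum(from * to)))
}

# evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive n reproducible child seeds (< 2^31) from one parent seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# inverse-CDF truncated normal draws; sd = 0 collapses to the clamped mean
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper || sd == 0)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# NA-aware centered boxcar mean of width k (odd); partial windows at the
# edges are renormalised over the frames actually available
smooth_boxcar <- function(x, k = 5) {
  stopifnot(k >= 1, k %% 2 == 1)
  n <- length(x)
  if (n == 0) return(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, xz))
  ci <- cumsum(c(0, as.numeric(ok)))
  h <- (k - 1) / 2
  i <- seq_len(n)
  lo <- pmax(0, i - h - 1)
  hi <- pmin(n, i + h)
  num <- cs[hi + 1] - cs[lo + 1]
  den <- ci[hi + 1] - ci[lo + 1]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Viewing-distance and angular-subtense geometry
#'
#' `viewing_distance_m()` returns the distance at which an object of physical
#' size `size_m` subtends `angle_deg` degrees of visual angle;
#' `visual_angle_deg()` is the inverse; `scaled_subtense_deg()` rescales a
#' subtense to a part of the object (e.g. the eyes within a head), assuming
#' the small-angle proportionality of sizes at a common distance.
#'
#' @param size_m Physical size in metres.
#' @param angle_deg Subtended visual angle in degrees.
#' @param distance_m Viewing distance in metres.
#' @param part_m,whole_m Physical sizes (metres) of the part and the whole.
#' @return A numeric scalar (metres or degrees).
#' @examples
#' viewing_distance_m(0.24, 1.47) # ~9.35 m
#' scaled_subtense_deg(1.47, 0.024, 0.24) # 0.147 deg
#' @export
viewing_distance_m <- function(size_m, angle_deg) {
  stopifnot(size_m > 0, angle_deg > 0, angle_deg < 180)
  size_m / (2 * tan(deg2rad(angle_deg) / 2))
}

#' @rdname viewing_distance_m
#' @export
visual_angle_deg <- function(size_m, distance_m) {
  stopifnot(size_m > 0, distance_m > 0)
  rad2deg(2 * atan(size_m / (2 * distance_m)))
}

#' @rdname viewing_distance_m
#' @export
scaled_subtense_deg <- function(angle_deg, part_m, whole_m) {
  stopifnot(angle_deg > 0, part_m > 0, whole_m > 0)
  angle_deg * part_m / whole_m
}
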