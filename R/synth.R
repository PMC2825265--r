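#' Specification of a Gaussian-mixture benchmark
#'
#' Describes an axis-aligned Gaussian mixture in feature space, used as a
#' benchmark with known ground truth for the clustering and validation
#' machinery.
#'
#' @param means k x F matrix of component means.
#' @param sds k x F matrix (or length-k vector, recycled across features) of
#'   component standard deviations, all > 0.
#' @param weights k mixing weights, summing to 1.
#' @param n total number of points.
#' @param seed RNG seed making the draw reproducible.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(means, sds, weights, n, seed = 1L) {
  means <- as.matrix(means)
  k <- nrow(means)
  if (is.vector(sds) || length(sds) == k)
    sds <- matrix(rep(as.numeric(sds), ncol(means)), k, ncol(means))
  sds <- as.matrix(sds)
  if (!all(dim(sds) == dim(means)))
    stop("sds must match the dimensions of means")
  if (any(sds <= 0)) stop("component sds must be strictly positive")
  weights <- as.numeric(weights)
  if (length(weights) != k) stop("need one weight per component")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (n < 1) stop("n must be positive")
  structure(list(k = k, means = means, sds = sds, weights = weights,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Sample a Gaussian mixture with ground-truth labels
#'
#' @param spec a [mixture_spec()].
#' @return list with `features` (a [feature_matrix()]) and `labels`
#'   (integer component of each point). Identical seeds give identical
#'   output.
#' @export
gaussian_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  labels <- sample.int(spec$k, spec$n, replace = TRUE, prob = spec$weights)
  f <- ncol(spec$means)
  vals <- spec$means[labels, , drop = FALSE] +
    matrix(stats::rnorm(spec$n * f), spec$n, f) * spec$sds[labels, , drop = FALSE]
  colnames(vals) <- paste0("f", seq_len(f))
  list(features = feature_matrix(vals), labels = labels)
}

#' Default artificial benchmark: five well-separated 2-D clusters
#'
#' An emulation of the classic five-cloud artificial benchmark: five
#' axis-aligned 2-D Gaussian components with unequal weights whose mean
#' separation is at least eight component standard deviations, n = 500,
#' fixed seed. On this data the Ward cost curve shows its largest jump when
#' merging below five clusters, and the full validation scan selects k = 5.
#'
#' @param n total points (default 500).
#' @param seed RNG seed (default 42).
#' @return a [mixture_spec()].
#' @export
default_artificial_spec <- function(n = 500L, seed = 42L) {
  # regular-pentagon cloud positions: every cluster has the same
  # nearest-neighbour distance and no cluster sits isolated at the rim of
  # the arrangement, giving the benchmark its distinct five-cluster
  # structure (merged solutions always pay a large within-cluster variance
  # without any cluster gaining much separation)
  ang <- pi / 2 + 2 * pi * (0:4) / 5
  means <- cbind(5 + 5 * cos(ang), 5 + 5 * sin(ang))
  mixture_spec(means, sds = rep(0.7, 5),
               weights = c(0.30, 0.25, 0.20, 0.15, 0.10),
               n = n, seed = seed)
}

#' Specification of a fly-like saccadic flight
#'
#' Describes a semi-Markov alternation between translational intersaccade
#' states and brief rotational saccade states. Within a state the six
#' body-frame velocities are the state mean plus Gaussian noise; state dwell
#' times are gamma distributed; saccades are much shorter than
#' intersaccades. The trajectory is obtained by integrating the body-frame
#' velocities (the exact inverse of [body_frame_velocities()]).
#'
#' @param states data frame with columns `name`, `group` ("saccade" or
#'   "intersaccade") and the six mean velocities `forward`, `sideward`,
#'   `upward` (m/s), `yaw_vel`, `pitch_vel`, `roll_vel` (deg/ms).
#' @param noise_trans,noise_rot named vectors (names "saccade",
#'   "intersaccade") of velocity noise standard deviations, translational in
#'   m/s and rotational in deg/ms.
#' @param dwell_mean named vector of mean dwell times in ms; the saccade
#'   mean must be below the intersaccade mean.
#' @param dwell_shape gamma shape parameter of the dwell distributions.
#' @param dt sampling step (ms); `duration` total flight time (ms).
#' @param seed RNG seed.
#' @return an object of class `flight_spec`.
#' @export
flight_spec <- function(states,
                        noise_trans = c(saccade = 0.06, intersaccade = 0.04),
                        noise_rot = c(saccade = 0.08, intersaccade = 0.03),
                        dwell_mean = c(saccade = 12, intersaccade = 40),
                        dwell_shape = 4, dt = 1, duration = 60000,
                        seed = 1L) {
  need <- c("name", "group", "forward", "sideward", "upward",
            "yaw_vel", "pitch_vel", "roll_vel")
  if (!all(need %in% names(states)))
    stop("states must have columns: ", paste(need, collapse = ", "))
  if (!all(states$group %in% c("saccade", "intersaccade")))
    stop("state groups must be 'saccade' or 'intersaccade'")
  if (!all(c("saccade", "intersaccade") %in% states$group))
    stop("need at least one saccade and one intersaccade state")
  if (any(dwell_mean <= 0)) stop("dwell means must be positive")
  if (dwell_mean[["saccade"]] >= dwell_mean[["intersaccade"]])
    stop("saccades must be shorter than intersaccades on average")
  if (duration < 2 * dt) stop("duration too short")
  structure(list(states = states, noise_trans = noise_trans,
                 noise_rot = noise_rot, dwell_mean = dwell_mean,
                 dwell_shape = dwell_shape, dt = dt, duration = duration,
                 seed = as.integer(seed)),
            class = "flight_spec")
}

#' Default fly-like flight specification
#'
#' Four saccade states and five intersaccade states patterned on blowfly
#' cruising flight: saccades combine a yaw velocity of +/-1.1 deg/ms with a
#' same-sign roll of 0.3 deg/ms (a left turn comes with a clockwise roll),
#' head-up or head-down pitch variants of +/-0.2 deg/ms, and a forward
#' velocity of 0.4 m/s; intersaccades are almost purely translational, with
#' forward velocities spanning 0.23 to 0.64 m/s coupled to downward
#' velocities of 0.02 to 0.31 m/s and symmetric sideward variants of
#' +/-0.15 m/s. Saccade dwell times average 12 ms, intersaccades 40 ms
#' (gamma, shape 4), so that few saccades but about half of the
#' intersaccades last longer than 20 ms.
#'
#' @param duration total flight time in ms (default 60000 = 60 s).
#' @param seed RNG seed.
#' @return a [flight_spec()].
#' @export
default_flight_spec <- function(duration = 60000, seed = 1L) {
  states <- data.frame(
    name = c("sacc_left_up", "sacc_left_down", "sacc_right_up",
             "sacc_right_down",
             "is_slow", "is_mid", "is_fast", "is_left", "is_right"),
    group = c(rep("saccade", 4), rep("intersaccade", 5)),
    forward  = c(0.40, 0.40, 0.40, 0.40, 0.23, 0.40, 0.64, 0.45, 0.45),
    sideward = c(0, 0, 0, 0, 0, 0, 0, 0.15, -0.15),
    upward   = c(0, 0, 0, 0, -0.02, -0.15, -0.31, -0.10, -0.10),
    yaw_vel  = c(1.1, 1.1, -1.1, -1.1, 0, 0, 0, 0, 0),
    pitch_vel = c(-0.2, 0.2, -0.2, 0.2, 0, 0, 0, 0, 0),
    roll_vel = c(0.3, 0.3, -0.3, -0.3, 0, 0, 0, 0, 0))
  flight_spec(states, duration = duration, seed = seed)
}

#' Simulate a saccadic flight trajectory with ground truth
#'
#' Draws the semi-Markov state sequence (alternating between the saccade and
#' intersaccade groups, states within the entered group chosen uniformly,
#' gamma dwell times), generates noisy body-frame velocities per millisecond
#' step, and integrates them into a world-frame 6-DOF trajectory: position
#' advances by the body velocity rotated into the world frame, orientation
#' by the rotation exponential of the angular rates. Feeding the result
#' through [body_frame_velocities()] recovers the generated velocities
#' exactly (the two operations are inverse discretisations).
#'
#' @param spec a [flight_spec()].
#' @return list with `trajectory` (a [trajectory6d()] of T+1 samples),
#'   `states` (integer ground-truth state index per velocity step, length
#'   T), `velocities` (T x 6 matrix of generated body-frame velocities) and
#'   `spec`.
#' @export
simulate_flight <- function(spec) {
  stopifnot(inherits(spec, "flight_spec"))
  set.seed(spec$seed)
  n_steps <- floor(spec$duration / spec$dt)
  st <- spec$states
  sacc <- which(st$group == "saccade")
  inter <- which(st$group == "intersaccade")
  # state sequence: start in an intersaccade, then alternate groups
  states <- integer(0)
  in_saccade <- FALSE
  while (length(states) < n_steps) {
    pool <- if (in_saccade) sacc else inter
    s <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
    grp <- if (in_saccade) "saccade" else "intersaccade"
    dwell <- max(1L, round(stats::rgamma(
      1, shape = spec$dwell_shape,
      scale = spec$dwell_mean[[grp]] / spec$dwell_shape) / spec$dt))
    states <- c(states, rep(s, dwell))
    in_saccade <- !in_saccade
  }
  states <- states[seq_len(n_steps)]
  vel_cols <- c("forward", "sideward", "upward",
                "yaw_vel", "pitch_vel", "roll_vel")
  v <- as.matrix(st[states, vel_cols])
  grp_of <- st$group[states]
  nt <- spec$noise_trans[grp_of]
  nr <- spec$noise_rot[grp_of]
  v[, 1:3] <- v[, 1:3] + matrix(stats::rnorm(3 * n_steps), n_steps, 3) * nt
  v[, 4:6] <- v[, 4:6] + matrix(stats::rnorm(3 * n_steps), n_steps, 3) * nr
  dimnames(v) <- list(NULL, vel_cols)

  dt_s <- spec$dt / 1000
  pos <- matrix(0, n_steps + 1L, 3)
  ori <- matrix(0, n_steps + 1L, 3)
  R <- diag(3)
  d2r <- pi / 180
  for (i in seq_len(n_steps)) {
    pos[i + 1L, ] <- pos[i, ] + R %*% (v[i, 1:3] * dt_s)
    # rotation vector about body axes: (roll, pitch, yaw) rates, deg/ms -> rad/step
    w <- c(v[i, 6], v[i, 5], v[i, 4]) * spec$dt * d2r
    R <- R %*% rotvec_to_matrix(w)
    ori[i + 1L, ] <- matrix_to_euler(R)
  }
  traj <- trajectory6d(t = seq(0, by = spec$dt, length.out = n_steps + 1L),
                       pos = pos, ori = ori)
  list(trajectory = traj, states = states, velocities = v, spec = spec)
}
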