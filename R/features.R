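#' Zero-phase Butterworth smoothing of a trajectory
#'
#' Applies a low-pass Butterworth filter twice, forward and backward, to each
#' of the six trajectory channels, giving zero phase distortion (an event in
#' the input stays put in the output). The effective magnitude response is
#' the squared single-pass response \eqn{|H(f)|^2}. Edge transients are
#' suppressed by odd-reflection padding of each channel before filtering.
#'
#' @param traj a [trajectory6d()].
#' @param order filter order of the single pass (default 2).
#' @param rel_cutoff relative border frequency as a fraction of the Nyquist
#'   frequency, in (0, 1); default 0.1.
#' @return a smoothed [trajectory6d()] with unchanged time stamps.
#' @export
smooth_trajectory <- function(traj, order = 2L, rel_cutoff = 0.1) {
  stopifnot(inherits(traj, "trajectory6d"))
  if (!(rel_cutoff > 0 && rel_cutoff < 1))
    stop("rel_cutoff must lie strictly between 0 and 1")
  n <- length(traj$t)
  if (n <= 3L * order)
    stop("trajectory too short to smooth: need more than ", 3L * order,
         " samples, got ", n)
  bf <- signal::butter(order, rel_cutoff, type = "low")
  ch <- cbind(traj$pos, traj$ori)
  sm <- apply(ch, 2, filtfilt_padded, b = bf$b, a = bf$a)
  trajectory6d(traj$t, sm[, 1:3, drop = FALSE], sm[, 4:6, drop = FALSE])
}

# Zero-phase IIR filtering with odd-reflection edge padding.
# The padded signal starts at exactly x[1] (its deviation from x[1] is zero),
# so filtering the deviation with zero initial state and adding x[1] back
# (valid because the low-pass has unit DC gain) leaves no startup transient
# for locally smooth signals; the pad absorbs what remains.
filtfilt_padded <- function(x, b, a) {
  n <- length(x)
  pad <- min(n - 1L, 10L * max(length(a), length(b)))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z - z[1])) + z[1]
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[(pad + 1L):(pad + n)]
}

#' Body-frame velocity features from a trajectory
#'
#' Turns a (smoothed) 6-DOF trajectory into the six velocity features used
#' for prototype discovery. For each step the world-frame displacement from
#' time step i to i+1 is rotated into the body frame at time i, giving the
#' forward, sideward and upward translational velocities (m/s); the relative
#' rotation from i to i+1, expressed in the body frame at time i, is
#' converted to yaw, pitch and roll angular rates (deg/ms) via the rotation
#' logarithm (exact, not a small-angle approximation, though at 1 ms sampling
#' and animal-scale rates the two agree to < 0.1%).
#'
#' Because the differences are expressed in the animal's own frame, the
#' features are invariant to where the animal is and which way it faces in
#' the arena: rigidly rotating or translating the whole trajectory in the
#' world frame leaves the feature matrix unchanged.
#'
#' The forward difference leaves no velocity row for the last trajectory
#' sample; feature row i carries time stamp t[i].
#'
#' @param traj a [trajectory6d()] (normally smoothed first,
#'   [smooth_trajectory()]).
#' @return a [feature_matrix()] with T-1 rows and columns
#'   `forward, sideward, upward` (m/s) and `yaw_vel, pitch_vel, roll_vel`
#'   (deg/ms).
#' @export
body_frame_velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory6d"))
  n <- length(traj$t)
  if (n < 2L) stop("need at least 2 samples to form velocities")
  dt <- traj$dt
  i0 <- seq_len(n - 1L)
  i1 <- i0 + 1L
  R <- euler_to_matrix_vec(traj$ori[, 1], traj$ori[, 2], traj$ori[, 3])

  dx <- traj$pos[i1, 1] - traj$pos[i0, 1]
  dy <- traj$pos[i1, 2] - traj$pos[i0, 2]
  dz <- traj$pos[i1, 3] - traj$pos[i0, 3]
  dts <- dt / 1000  # velocity in m/s while dt is in ms
  # v_body = R_i^T %*% d, components via column dot products
  fwd <- (R$R11[i0] * dx + R$R21[i0] * dy + R$R31[i0] * dz) / dts
  sid <- (R$R12[i0] * dx + R$R22[i0] * dy + R$R32[i0] * dz) / dts
  upw <- (R$R13[i0] * dx + R$R23[i0] * dy + R$R33[i0] * dz) / dts

  # relative rotation Q = R_i^T %*% R_{i+1}, entries vectorised
  q <- function(r, c) {
    R[[paste0("R", 1, r)]][i0] * R[[paste0("R", 1, c)]][i1] +
      R[[paste0("R", 2, r)]][i0] * R[[paste0("R", 2, c)]][i1] +
      R[[paste0("R", 3, r)]][i0] * R[[paste0("R", 3, c)]][i1]
  }
  Q11 <- q(1, 1); Q22 <- q(2, 2); Q33 <- q(3, 3)
  v1 <- q(3, 2) - q(2, 3)   # 2*sin(theta)*axis_x
  v2 <- q(1, 3) - q(3, 1)
  v3 <- q(2, 1) - q(1, 2)
  ca <- pmin(1, pmax(-1, (Q11 + Q22 + Q33 - 1) / 2))
  th <- acos(ca)
  scale <- ifelse(th < 1e-7, 0.5, th / (2 * sin(th)))
  # rotation vector components about body x (roll), y (pitch), z (yaw)
  wx <- v1 * scale; wy <- v2 * scale; wz <- v3 * scale
  to_dpms <- 180 / pi / dt  # rad/step -> deg/ms
  feature_matrix(
    cbind(forward = fwd, sideward = sid, upward = upw,
          yaw_vel = wz * to_dpms, pitch_vel = wy * to_dpms,
          roll_vel = wx * to_dpms),
    units = c("m/s", "m/s", "m/s", "deg/ms", "deg/ms", "deg/ms"),
    t = traj$t[i0])
}

#' z-normalise a feature matrix
#'
#' Normalises each feature column individually to zero mean and standard
#' deviation one, so that all features contribute comparably to Euclidean
#' distances. The normalisation parameters are attached to the result for
#' later renormalisation of values ([renormalize_features()]) or of
#' centroids ([renormalize_centroids()]).
#'
#' @param fm a [feature_matrix()] (or bare numeric matrix).
#' @param params optional pre-computed normalisation parameters (list with
#'   `mean` and `sd`); when supplied these are applied instead of
#'   re-estimating, so that data subsets live in the same normalised space
#'   as the full set.
#' @return a z-normalised [feature_matrix()] with `norm` attached.
#' @export
znormalize <- function(fm, params = NULL) {
  fm <- as_feature_matrix(fm)
  if (is.null(params)) {
    m <- colMeans(fm$values)
    s <- apply(fm$values, 2, stats::sd)
    zero <- which(s <= 0 | !is.finite(s))
    if (length(zero) > 0)
      stop("cannot normalise constant feature(s): ",
           paste(colnames(fm$values)[zero], collapse = ", "))
    params <- list(mean = as.numeric(m), sd = as.numeric(s))
  } else {
    params <- validate_norm(params, ncol(fm$values))
  }
  vals <- sweep(sweep(fm$values, 2, params$mean, "-"), 2, params$sd, "/")
  feature_matrix(vals, colnames(fm$values), fm$units, fm$t, params)
}

#' Undo z-normalisation of a feature matrix
#'
#' @param fm a z-normalised [feature_matrix()] with `norm` attached.
#' @return the [feature_matrix()] in original (physical) units, `norm`
#'   removed.
#' @export
renormalize_features <- function(fm) {
  fm <- as_feature_matrix(fm)
  if (is.null(fm$norm))
    stop("feature matrix carries no normalisation parameters")
  vals <- sweep(sweep(fm$values, 2, fm$norm$sd, "*"), 2, fm$norm$mean, "+")
  feature_matrix(vals, colnames(fm$values), fm$units, fm$t, NULL)
}

#' Express centroids in physical units (feature prototypes)
#'
#' Maps a centroid set from z-normalised feature space back to physical
#' units: `centroid * sd + mean` per feature; the per-cluster feature
#' standard deviations scale by `sd`. The result is the set of feature
#' prototypes (e.g. velocities in m/s and deg/ms).
#'
#' @param cs a [centroid_set()] whose `norm` parameters are present.
#' @return a [centroid_set()] in physical units (`norm` removed).
#' @export
renormalize_centroids <- function(cs) {
  stopifnot(inherits(cs, "centroid_set"))
  if (is.null(cs$norm))
    stop("centroid set carries no normalisation parameters")
  cent <- sweep(sweep(cs$centroids, 2, cs$norm$sd, "*"), 2, cs$norm$mean, "+")
  fsd <- if (!is.null(cs$feature_sd))
    sweep(cs$feature_sd, 2, cs$norm$sd, "*")
  centroid_set(cent, cs$shares, cs$within_var, fsd, norm = NULL,
               units = cs$units, objective = cs$objective)
}

#' PCA diagnostic for feature groups
#'
#' Runs principal component analysis independently on groups of features
#' (typically the three translational and the three rotational velocities)
#' to show how the variance in each group spreads over its components. A
#' strongly dominant first component would indicate that the group could be
#' represented in fewer dimensions; evenly spread variance argues for
#' keeping all features.
#'
#' @param fm a [feature_matrix()].
#' @param groups named list of feature-name (or column-index) vectors, each
#'   of length >= 2, partitioning the features of interest.
#' @return a named list with one element per group, each of class
#'   `pca_diagnostic`: `variance_fraction` (descending, sums to 1) and
#'   `loadings` (component x feature matrix).
#' @export
pca_diagnostic <- function(fm, groups) {
  fm <- as_feature_matrix(fm)
  if (!is.list(groups) || length(groups) == 0)
    stop("groups must be a non-empty list of feature subsets")
  out <- lapply(groups, function(g) {
    if (length(g) < 2) stop("each feature group needs at least 2 features")
    sub <- fm$values[, g, drop = FALSE]
    p <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
    frac <- p$sdev^2 / sum(p$sdev^2)
    structure(list(variance_fraction = frac, loadings = t(p$rotation)),
              class = "pca_diagnostic")
  })
  out
}

#' @export
print.pca_diagnostic <- function(x, ...) {
  cat("PCA diagnostic: variance fractions ",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
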