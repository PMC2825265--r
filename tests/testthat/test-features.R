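test_that("zero-phase smoothing passes DC and preserves symmetry", {
  n <- 200
  tr <- trajectory6d(seq_len(n) - 1,
                     cbind(rep(1.5, n), rep(-2, n), rep(0.25, n)),
                     cbind(rep(30, n), rep(-10, n), rep(5, n)))
  sm <- smooth_trajectory(tr)
  expect_equal(sm$pos, tr$pos, tolerance = 1e-9)
  expect_equal(sm$ori, tr$ori, tolerance = 1e-9)
  expect_identical(sm$t, tr$t)

  # symmetric triangular pulse on x stays symmetric about its centre
  n <- 401
  x <- pmax(0, 50 - abs(seq_len(n) - 201))
  tr <- trajectory6d(seq_len(n) - 1, cbind(x, 0, 0), matrix(0, n, 3))
  y <- smooth_trajectory(tr)$pos[, 1]
  expect_lt(max(abs(y - rev(y))), 1e-9)
})

test_that("smoothing gain matches the squared Butterworth magnitude response", {
  # two passes of an order-n Butterworth give |H(f)|^2 = 1/(1 + (f/fc)^(2n))
  n <- 1000
  f_rel <- 0.4    # of Nyquist; cutoff 0.1 of Nyquist
  x <- sin(pi * f_rel * (seq_len(n) - 1))
  tr <- trajectory6d(seq_len(n) - 1, cbind(x, 0, 0), matrix(0, n, 3))
  y <- smooth_trajectory(tr, order = 2, rel_cutoff = 0.1)$pos[, 1]
  mid <- 301:700   # avoid residual edge effects
  basis <- cbind(sin(pi * f_rel * (mid - 1)), cos(pi * f_rel * (mid - 1)))
  amp <- sqrt(sum(stats::lm.fit(basis, y[mid])$coefficients^2))
  expected <- 1 / (1 + (f_rel / 0.1)^4)
  expect_equal(amp, expected, tolerance = 0.02)
})

test_that("smoothing rejects too-short input and bad cutoffs", {
  tr <- straight_trajectory(n = 5)
  expect_error(smooth_trajectory(tr), "too short")
  expect_error(smooth_trajectory(straight_trajectory(20), rel_cutoff = 1.2),
               "rel_cutoff")
})

test_that("body-frame velocities honour the frame conventions", {
  # facing +y (yaw 90), moving along world +x: pure sideward motion
  tr <- straight_trajectory(n = 6, v = c(0.5, 0, 0), yaw = 90)
  v <- body_frame_velocities(tr)
  expect_equal(nrow(v$values), 5)
  expect_equal(abs(v$values[, "sideward"]), rep(0.5, 5), tolerance = 1e-9)
  expect_equal(v$values[, "forward"], rep(0, 5), tolerance = 1e-9)
  expect_equal(max(abs(v$values[, 4:6])), 0, tolerance = 1e-9)

  # pure yaw rotation of 1 deg per ms: yaw velocity 1 deg/ms, rest 0
  n <- 8
  tr <- trajectory6d(seq_len(n) - 1, matrix(0, n, 3),
                     cbind(seq_len(n) - 1, 0, 0))
  v <- body_frame_velocities(tr)$values
  expect_equal(v[, "yaw_vel"], rep(1, n - 1), tolerance = 1e-9)
  expect_equal(max(abs(v[, colnames(v) != "yaw_vel"])), 0, tolerance = 1e-9)

  # feature row i carries the time stamp of trajectory sample i
  expect_equal(body_frame_velocities(straight_trajectory(5))$t, 0:3)
})

test_that("circular flight gives constant forward speed and yaw rate", {
  # heading tangent to a circle: forward ~ v, sideward ~ 0, yaw ~ omega
  omega <- 0.5                 # deg/ms
  v_ms <- 0.4                  # m/s
  n <- 400
  t <- seq_len(n) - 1
  th <- omega * t * pi / 180   # heading angle in rad
  R <- v_ms / (omega * pi / 180 * 1000)   # radius in m
  tr <- trajectory6d(t, cbind(R * sin(th), R * (1 - cos(th)), 0),
                     cbind(omega * t, 0, 0))
  f <- body_frame_velocities(tr)$values
  tol <- omega * pi / 180 * v_ms * 2      # discretisation error O(omega*dt)
  expect_equal(f[, "forward"], rep(v_ms, n - 1), tolerance = tol)
  expect_lt(max(abs(f[, "sideward"])), tol)
  expect_equal(f[, "yaw_vel"], rep(omega, n - 1), tolerance = 1e-6)
})

test_that("features are invariant under rigid world rotation of the trajectory", {
  set.seed(11)
  sim <- simulate_flight(default_flight_spec(duration = 300, seed = 4))
  tr <- sim$trajectory
  R0 <- ethoproto:::euler_to_matrix(35, -20, 60)
  tr_rot <- rotate_world(tr, R0)
  f1 <- body_frame_velocities(tr)$values
  f2 <- body_frame_velocities(tr_rot)$values
  expect_equal(f2, f1, tolerance = 1e-8)
})

test_that("z-normalisation is exact, invertible and rejects constants", {
  fm <- feature_matrix(cbind(a = c(1, 2, 3), b = c(-5, 0, 20)))
  z <- znormalize(fm)
  expect_lt(max(abs(colMeans(z$values))), 1e-8)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-8)
  expect_equal(renormalize_features(z)$values, fm$values, tolerance = 1e-10)

  expect_error(znormalize(feature_matrix(cbind(a = c(1, 1, 1), b = 1:3))),
               "constant feature.*a")

  # applying stored parameters to a subset keeps one common space
  sub <- znormalize(fm_sub <- feature_matrix(fm$values[1:2, ]),
                    params = z$norm)
  expect_equal(sub$values, z$values[1:2, ], tolerance = 1e-12)
})

test_that("centroid renormalisation applies mean/sd per feature", {
  cs <- centroid_set(matrix(2, 1, 1), 1, 0, feature_sd = matrix(1.5, 1, 1),
                     norm = list(mean = 0.1, sd = 0.3))
  out <- renormalize_centroids(cs)
  expect_equal(out$centroids[1, 1], 0.7)
  expect_equal(out$feature_sd[1, 1], 0.45)
  expect_null(out$norm)

  ident <- centroid_set(matrix(c(1, -2), 1, 2), 1, 0,
                        norm = list(mean = c(0, 0), sd = c(1, 1)))
  expect_equal(renormalize_centroids(ident)$centroids, ident$centroids)
  expect_error(renormalize_centroids(renormalize_centroids(ident)),
               "no normalisation")

  # z-normalise then renormalise is an identity on centroids
  fm <- feature_matrix(matrix(rnorm(60, 4, 3), 30, 2))
  z <- znormalize(fm)
  cs2 <- lloyd(z, 3, seed = 1)
  phys <- renormalize_centroids(cs2)
  rez <- sweep(sweep(phys$centroids, 2, z$norm$mean, "-"), 2, z$norm$sd, "/")
  expect_equal(rez, cs2$centroids, tolerance = 1e-10)
})

test_that("PCA diagnostic fractions behave like variance shares", {
  set.seed(21)
  iso <- feature_matrix(matrix(rnorm(30000), 10000, 3))
  d <- pca_diagnostic(iso, list(all = 1:3))$all
  expect_equal(d$variance_fraction, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(sum(d$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(d$variance_fraction) <= 1e-12))

  line <- feature_matrix(cbind(1:50, 2 * (1:50)))
  dl <- pca_diagnostic(line, list(g = 1:2))$g
  expect_equal(dl$variance_fraction, c(1, 0), tolerance = 1e-9)

  expect_error(pca_diagnostic(iso, list(g = 1)), "at least 2")
})
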