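test_that("leave-out plans have the prescribed cardinality and coverage", {
  plan <- leave_out_plan(1000, 0.1, 50)
  expect_length(plan$masks, 50)
  expect_true(all(vapply(plan$masks, length, integer(1)) == 900))

  # N = 10, 50% at two positions: keep {6..10} then {1..5} (1-based)
  p2 <- leave_out_plan(10, 0.5, 2)
  expect_equal(p2$masks[[1]], 6:10)
  expect_equal(p2$masks[[2]], 1:5)

  # every index is kept in at least one mask
  for (n in c(100, 257, 1000)) {
    for (f in c(0.1, 0.2, 0.5)) {
      kept <- sort(unique(unlist(leave_out_plan(n, f, 50)$masks)))
      expect_equal(kept, seq_len(n))
    }
  }

  expect_error(leave_out_plan(100, 1.2), "between 0 and 1")
  expect_error(leave_out_plan(100, 0), "between 0 and 1")
})

test_that("leave-out blocks wrap around the sequence end", {
  p <- leave_out_plan(10, 0.3, 10)
  # position 9 (0-based start 9 of block length 3) drops {10, 1, 2}
  expect_equal(p$masks[[10]], 3:9)
})

test_that("match_distance is zero on permutations and exact on hand cases", {
  set.seed(12)
  cent <- matrix(rnorm(12), 4, 3)
  a <- centroid_set(cent, rep(0.25, 4), rep(0, 4))
  b <- centroid_set(cent[c(3, 1, 4, 2), ], rep(0.25, 4), rep(0, 4))
  expect_equal(match_distance(a, b)$distance, 0, tolerance = 1e-12)

  # A = {(0,0),(1,1)}, B = {(1,1),(0,0.5)}: distance 0.25 / (2*2)
  A <- centroid_set(rbind(c(0, 0), c(1, 1)), c(0.5, 0.5), c(0, 0))
  B <- centroid_set(rbind(c(1, 1), c(0, 0.5)), c(0.5, 0.5), c(0, 0))
  md <- match_distance(A, B)
  expect_equal(md$distance, 0.0625)
  expect_equal(md$matching, c(2L, 1L))

  expect_error(match_distance(A, centroid_set(matrix(0, 3, 2),
                                              rep(1 / 3, 3), rep(0, 3))),
               "cardinality")
})

test_that("Hungarian matching equals the exhaustive permutation minimum", {
  set.seed(14)
  P <- all_perms(6)
  for (r in 1:10) {
    ca <- matrix(rnorm(36), 6, 6)
    cb <- matrix(rnorm(36), 6, 6)
    a <- centroid_set(ca, rep(1 / 6, 6), rep(0, 6))
    b <- centroid_set(cb, rep(1 / 6, 6), rep(0, 6))
    got <- match_distance(a, b)$distance
    cost <- ethoproto:::sq_dist_to_centroids(ca, cb, "naive")
    brute <- min(apply(P, 1, function(p) sum(cost[cbind(1:6, p)]))) / 36
    expect_equal(got, brute, tolerance = 1e-9)
  }
})

test_that("match_distance behaves like a pseudometric", {
  set.seed(15)
  mk <- function() centroid_set(matrix(rnorm(8), 4, 2), rep(0.25, 4),
                                rep(0, 4))
  for (r in 1:100) {
    a <- mk(); b <- mk(); c <- mk()
    dab <- match_distance(a, b)$distance
    dba <- match_distance(b, a)$distance
    dac <- match_distance(a, c)$distance
    dcb <- match_distance(c, b)$distance
    expect_equal(dab, dba, tolerance = 1e-12)
    # the matched sum of *squared* distances is not itself a metric; its
    # square root is (the quotient of the stacked L2 metric under
    # centroid relabelling), so the triangle inequality holds on roots
    expect_gte(sqrt(dac) + sqrt(dcb), sqrt(dab) - 1e-9)
  }
})

test_that("mean set selection follows the smallest mean distance", {
  one <- function(v) centroid_set(matrix(v, 1, 1), 1, 0)
  sets <- list(one(0), one(1), one(5))
  sr <- mean_set(sets)
  # squared distances: d(0,1)=1, d(0,5)=25, d(1,5)=16
  # mean distance to others: {0}: 13, {1}: 8.5, {5}: 20.5
  expect_equal(sr$mean_set_index, 2L)
  expect_equal(sr$instability, 8.5)
  expect_equal(sr$mean_error, sd(c(1, 16)) / 3)

  # identical sets: zero instability
  same <- replicate(4, one(2), simplify = FALSE)
  expect_equal(mean_set(same)$instability, 0)

  # instability invariant under permuting the list
  expect_equal(mean_set(sets[c(3, 1, 2)])$instability, sr$instability)
  expect_error(mean_set(sets[1]), "at least 2")
})

test_that("cluster quality matches hand computation and brute force", {
  # members {-1.1,-0.9} and {0.9,1.1} around centroids -1 and +1
  fm <- feature_matrix(matrix(c(-1.1, -0.9, 0.9, 1.1), 4, 1))
  cs <- centroid_set(matrix(c(-1, 1), 2, 1), c(0.5, 0.5), c(0.01, 0.01))
  q <- cluster_quality(fm, cs)
  expect_equal(q$inner, c(0.01, 0.01))
  expect_equal(q$outer, c(4, 4))
  expect_equal(q$per_cluster_q, c(400, 400))
  expect_equal(q$mean_q, 400)

  # duplicating every data point leaves Q unchanged
  fm2 <- feature_matrix(fm$values[rep(1:4, 2), , drop = FALSE])
  expect_equal(cluster_quality(fm2, cs)$per_cluster_q, q$per_cluster_q)

  # brute-force oracle on the five-blob benchmark
  gm <- gaussian_mixture(default_artificial_spec(n = 200, seed = 3))
  fmz <- znormalize(gm$features)
  cs5 <- restarted_kmeans(fmz, 5, n_restarts = 6, base_seed = 2)
  got <- cluster_quality(fmz, cs5)
  lab <- apply(fmz$values, 1, function(p)
    which.min(colSums((t(cs5$centroids) - p)^2)))
  inner <- vapply(1:5, function(j)
    mean(colSums((t(fmz$values[lab == j, , drop = FALSE]) -
                    cs5$centroids[j, ])^2)), numeric(1))
  outer <- vapply(1:5, function(j)
    min(colSums((t(cs5$centroids[-j, , drop = FALSE]) -
                   cs5$centroids[j, ])^2)), numeric(1))
  expect_equal(got$per_cluster_q, outer / inner, tolerance = 1e-9)
})

test_that("quality increases when a cluster contracts toward its centroid", {
  set.seed(16)
  x <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             sweep(matrix(rnorm(100, 0, 0.5), 50, 2), 2, c(5, 5), "+"))
  cs <- restarted_kmeans(feature_matrix(x), 2, n_restarts = 3, base_seed = 1)
  lab <- assign_labels(feature_matrix(x), cs)
  q0 <- cluster_quality(feature_matrix(x), cs, lab)
  xc <- x
  j <- 1
  xc[lab == j, ] <- sweep(sweep(x[lab == j, ], 2, cs$centroids[j, ], "-") *
                            0.5, 2, cs$centroids[j, ], "+")
  q1 <- cluster_quality(feature_matrix(xc), cs, lab)
  expect_gt(q1$per_cluster_q[j], q0$per_cluster_q[j])
})

test_that("degenerate quality cases are flagged", {
  fm <- feature_matrix(matrix(c(0, 0, 1, 1), 4, 1))
  cs <- centroid_set(matrix(c(0, 1), 2, 1), c(0.5, 0.5), c(0, 0))
  expect_warning(q <- cluster_quality(fm, cs), "Inf")
  expect_true(all(!is.finite(q$per_cluster_q)))
  cs3 <- centroid_set(matrix(c(0, 1, 50), 3, 1), rep(1 / 3, 3), rep(0, 3))
  expect_error(cluster_quality(fm, cs3), "empty cluster")
})

test_that("select_k demands stability first, then maximal quality", {
  # single k scanned
  expect_equal(select_k(fake_report(4, 0.1, 2)), 4L)

  # k = 4 unstable with top quality, k = 5 stable: 5 wins
  rep1 <- fake_report(3:6, instability = c(0.001, 0.5, 0.002, 0.003),
                      quality = c(1, 10, 5, 2))
  expect_equal(select_k(rep1), 5L)

  # monotone quality but exploding instability at high k: a small k wins
  rep2 <- fake_report(2:8,
                      instability = c(0.001, 0.001, 0.002, 0.3, 0.5, 0.8, 1),
                      quality = 1:7)
  expect_equal(select_k(rep2), 4L)

  # absolute cap can render everything inadmissible
  expect_error(select_k(fake_report(2:3, c(0.5, 0.6), c(1, 2)),
                        abs_cap = 0.1), "no k is admissible")
})

test_that("the scan is reproducible and its report round-trips", {
  fm <- znormalize(blob_features(seed = 20, n_per = 40))
  args <- list(fm = fm, k_range = 2:4, fractions = 0.2, n_positions = 5,
               n_full_runs = 3, restarts = 3, base_seed = 9)
  r1 <- do.call(validation_scan, args)
  r2 <- do.call(validation_scan, args)
  expect_equal(r1$results, r2$results, tolerance = 1e-12)
  expect_equal(r1$selected_k, 3L)

  path <- withr::local_tempfile(fileext = ".json")
  write_report(r1, path)
  back <- read_report(path)
  expect_equal(back$selected_k, r1$selected_k)
  expect_equal(back$k_range, r1$k_range)
  for (k in as.character(2:4)) {
    expect_equal(back$results[[k]]$between$instability,
                 r1$results[[k]]$between$instability, tolerance = 1e-12)
    expect_equal(back$results[[k]]$within[["full"]]$pairwise,
                 r1$results[[k]]$within[["full"]]$pairwise,
                 tolerance = 1e-12)
    expect_equal(back$results[[k]]$quality[["full"]]$per_cluster_q,
                 r1$results[[k]]$quality[["full"]]$per_cluster_q,
                 tolerance = 1e-12)
  }
  expect_equal(select_k(back), r1$selected_k)
})

test_that("identical data under a single k gives zero instability", {
  fm <- znormalize(blob_features(seed = 22, n_per = 30,
                                 centers = rbind(c(0, 0), c(8, 8))))
  rep <- validation_scan(fm, 2, fractions = NULL, n_full_runs = 4,
                         restarts = 4, base_seed = 3)
  expect_lt(rep$results[["2"]]$within[["full"]]$instability, 1e-12)
  expect_equal(rep$selected_k, 2L)
})
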