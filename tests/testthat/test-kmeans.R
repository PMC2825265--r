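test_that("k = 1 gives the column means and the total variance", {
  set.seed(4)
  fm <- feature_matrix(matrix(rnorm(90, 2), 30, 3))
  cs <- lloyd(fm, 1, seed = 1)
  expect_equal(cs$centroids[1, ], colMeans(fm$values), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cs$objective, sum(sweep(fm$values, 2, colMeans(fm$values))^2),
               tolerance = 1e-10)
  expect_equal(cs$shares, 1)
})

test_that("two clean blobs are recovered with balanced shares", {
  set.seed(6)
  x <- rbind(matrix(rnorm(400, sd = 0.1), 200, 2),
             sweep(matrix(rnorm(400, sd = 0.1), 200, 2), 2, c(10, 10), "+"))
  cs <- restarted_kmeans(feature_matrix(x), 2, n_restarts = 5, base_seed = 1)
  cent <- cs$centroids[order(cs$centroids[, 1]), ]
  expect_lt(max(abs(cent - rbind(c(0, 0), c(10, 10)))), 0.05)
  expect_equal(cs$shares, c(0.5, 0.5), tolerance = 0.05)

  # independent cross-check against stats::kmeans on the same clean data
  km <- stats::kmeans(x, 2, nstart = 5)
  expect_equal(cs$objective, km$tot.withinss, tolerance = 1e-6)
})

test_that("the Lloyd objective never increases within a run", {
  set.seed(10)
  fm <- feature_matrix(matrix(rnorm(300), 100, 3))
  for (s in 1:5) {
    tr <- attr(lloyd(fm, 4, seed = s), "objective_trace")
    expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("lloyd is reproducible and validates k", {
  fm <- blob_features(seed = 2)
  a <- lloyd(fm, 3, seed = 7)
  b <- lloyd(fm, 3, seed = 7)
  expect_identical(a$centroids, b$centroids)
  expect_identical(attr(a, "labels"), attr(b, "labels"))
  expect_error(lloyd(fm, 0, seed = 1), "positive")
  expect_error(lloyd(fm, nrow(fm$values) + 1, seed = 1), "exceeds")
})

test_that("restarts select the best run and never do worse", {
  fm <- blob_features(seed = 3)
  single <- lloyd(fm, 3, seed = 5)
  expect_equal(restarted_kmeans(fm, 3, n_restarts = 1, base_seed = 5),
               single, ignore_attr = TRUE)
  objs <- vapply(5:14, function(s) lloyd(fm, 3, seed = s)$objective,
                 numeric(1))
  best <- restarted_kmeans(fm, 3, n_restarts = 10, base_seed = 5)
  expect_true(all(best$objective <= objs + 1e-12))
})

test_that("restarts escape a collapsed-centroid local optimum", {
  # three blobs; some single seeds collapse two centroids into one blob
  fm <- blob_features(seed = 19, n_per = 80,
                      centers = rbind(c(0, 0), c(12, 0), c(6, 10)))
  objs <- vapply(1:40, function(s) lloyd(fm, 3, seed = s)$objective,
                 numeric(1))
  expect_gt(max(objs), 2 * min(objs))   # bad local optima exist
  best <- restarted_kmeans(fm, 3, n_restarts = 10, base_seed = 1)
  cent <- best$centroids[order(best$centroids[, 1]), ]
  expect_lt(max(abs(cent - rbind(c(0, 0), c(6, 10), c(12, 0)))), 0.1)
})

test_that("assignment follows the nearest-centroid rule with low-index ties", {
  cs <- centroid_set(rbind(c(0, 0), c(2, 0), c(4, 0)),
                     shares = rep(1 / 3, 3), within_var = rep(0, 3))
  expect_equal(assign_labels(matrix(c(2, 0), 1, 2), cs), 2L)
  # (2, h) is equidistant from centroids 1 and 3: tie resolves to 1
  expect_equal(assign_labels(matrix(c(2, 5), 1, 2),
                             centroid_set(rbind(c(0, 0), c(9, 9), c(4, 0)),
                                          shares = rep(1 / 3, 3),
                                          within_var = rep(0, 3))), 1L)
  expect_error(assign_labels(matrix(0, 1, 3), cs), "dimension mismatch")
})

test_that("accelerated and naive assignment agree exactly on 10k points", {
  set.seed(23)
  x <- feature_matrix(matrix(runif(60000, -5, 5), 10000, 6))
  cs <- lloyd(x, 9, seed = 2)
  expect_identical(assign_labels(x, cs, method = "fast"),
                   assign_labels(x, cs, method = "naive"))
})

test_that("returned clusterings never contain empty clusters", {
  set.seed(31)
  for (s in 1:10) {
    fm <- feature_matrix(matrix(rnorm(60), 20, 3))
    cs <- lloyd(fm, 6, seed = s)
    expect_true(all(cs$shares > 0))
    expect_equal(sum(cs$shares), 1, tolerance = 1e-12)
  }
})
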