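test_that("Ward joining costs realise the variance-increase definition", {
  # two singletons: cost = ||x1 - x2||^2 / 2
  d <- ward_cluster(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(d$joining_costs, 25 / 2)

  # 1-D {0, 1, 10}: first merge {0,1} at 0.5, then (2*1/3)*(0.5-10)^2
  d3 <- ward_cluster(matrix(c(0, 1, 10), 3, 1))
  expect_equal(d3$joining_costs, c(0.5, (2 / 3) * (0.5 - 10)^2),
               tolerance = 1e-12)
  expect_equal(d3$merges$size[2], 3L)
})

test_that("joining costs telescope to the total variance", {
  set.seed(5)
  for (n in c(10, 40)) {
    x <- matrix(rnorm(3 * n), n, 3)
    d <- ward_cluster(x)
    total <- sum(sweep(x, 2, colMeans(x))^2)
    expect_equal(sum(d$joining_costs), total, tolerance = 1e-8)
    expect_true(all(d$joining_costs >= 0))
    expect_equal(nrow(d$merges), n - 1L)
  }
})

test_that("merge costs agree with brute-force greedy agglomeration", {
  set.seed(8)
  for (n in c(12, 30, 50)) {
    x <- matrix(rnorm(2 * n), n, 2)
    expect_equal(ward_cluster(x)$joining_costs, brute_ward_costs(x),
                 tolerance = 1e-10)
  }
})

test_that("the dendrogram is invariant under row permutation", {
  set.seed(13)
  x <- matrix(rnorm(60), 30, 2)
  perm <- sample(30)
  expect_equal(ward_cluster(x)$joining_costs,
               ward_cluster(x[perm, ])$joining_costs, tolerance = 1e-10)
})

test_that("size cap refuses oversized inputs with advice", {
  expect_error(ward_cluster(matrix(rnorm(30), 15, 2), max_n = 10),
               "subsample")
})

test_that("cost curve indexes costs by the from-cluster count", {
  d3 <- ward_cluster(matrix(c(0, 1, 10), 3, 1))
  cc <- cost_curve(d3)
  expect_equal(cc$num_clusters, c(3, 2))
  expect_equal(cc$cost, d3$joining_costs)
  expect_equal(cc$differential[2], diff(d3$joining_costs))

  # four well-separated point-pairs: the 2 -> 1 transition dominates m <= 4
  x <- rbind(c(0, 0), c(0, 0.2), c(100, 0), c(100, 0.2),
             c(0, 100), c(0, 100.2), c(100, 100), c(100, 100.2))
  cc4 <- cost_curve(ward_cluster(x))
  sub <- cc4[cc4$num_clusters <= 4 & !is.na(cc4$differential), ]
  expect_equal(sub$num_clusters[which.max(sub$differential)], 2)
})

test_that("five-blob data yields its cost jump when merging below five", {
  gm <- gaussian_mixture(default_artificial_spec(n = 300, seed = 2))
  cc <- cost_curve(ward_cluster(gm$features))
  # the 5 -> 4 merge is the first between-cloud merge: largest differential
  # among all transitions that keep at least five clusters
  keep <- cc$num_clusters >= 5 & !is.na(cc$differential)
  expect_equal(cc$num_clusters[keep][which.max(cc$differential[keep])], 5)

  rng <- suggest_k_range(cc)
  expect_true(rng[1] <= 5 && 5 <= rng[2])
})

test_that("flat curves fall back to the default range with a warning", {
  set.seed(17)
  noise <- feature_matrix(matrix(rnorm(400), 200, 2))
  cc <- cost_curve(ward_cluster(noise))
  expect_warning(rng <- suggest_k_range(cc), "fallback")
  expect_equal(as.integer(rng), c(2L, 50L))
})

test_that("a single large cost jump anchors the suggested range", {
  cost <- rep(1, 29)
  cost[match(3, 30:2)] <- 50
  cc <- structure(data.frame(num_clusters = 30:2, cost = cost,
                             differential = c(NA, diff(cost))),
                  class = c("cost_curve", "data.frame"))
  rng <- suggest_k_range(cc)
  expect_equal(attr(rng, "elbow"), 3)
  expect_equal(rng[2], 6)
})
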