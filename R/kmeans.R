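# Squared-Euclidean point-to-centroid distances.
# "naive" loops over centroids computing rowSums((x - c_j)^2) directly;
# "fast" expands the square and uses one BLAS cross-product. Both are exact
# evaluations of the same quantity; naive is the reference path, fast the
# accelerated one.
sq_dist_to_centroids <- function(x, cent, method = c("fast", "naive")) {
  method <- match.arg(method)
  k <- nrow(cent)
  if (ncol(x) != ncol(cent))
    stop("dimension mismatch: data has ", ncol(x), " features, centroids ",
         ncol(cent))
  if (method == "naive") {
    D <- matrix(0, nrow(x), k)
    for (j in seq_len(k))
      D[, j] <- rowSums(sweep(x, 2, cent[j, ], "-")^2)
    D
  } else {
    D <- rowSums(x^2) - 2 * tcrossprod(x, cent) +
      rep(rowSums(cent^2), each = nrow(x))
    pmax(D, 0)
  }
}

#' Assign points to their nearest centroid
#'
#' Labels each row of the feature matrix with the index of the centroid
#' minimising the squared Euclidean distance (the Voronoi partition). Ties
#' go to the lowest centroid index. The accelerated evaluation
#' (`method = "fast"`, the default) yields labels identical to the naive
#' per-centroid loop (`method = "naive"`).
#'
#' @param fm a [feature_matrix()] (or bare numeric matrix) in the same space
#'   as the centroids.
#' @param cs a [centroid_set()].
#' @param method distance evaluation path, `"fast"` or `"naive"`.
#' @return integer vector of centroid indices, one per row.
#' @export
assign_labels <- function(fm, cs, method = c("fast", "naive")) {
  fm <- as_feature_matrix(fm)
  stopifnot(inherits(cs, "centroid_set"))
  D <- sq_dist_to_centroids(fm$values, cs$centroids, match.arg(method))
  max.col(-D, ties.method = "first")
}

# per-cluster statistics given labels; sds use denominator n_j
cluster_stats <- function(x, cent, labels) {
  k <- nrow(cent)
  n <- nrow(x)
  shares <- tabulate(labels, k) / n
  within <- numeric(k)
  fsd <- matrix(0, k, ncol(x), dimnames = list(NULL, colnames(x)))
  for (j in seq_len(k)) {
    mem <- x[labels == j, , drop = FALSE]
    if (nrow(mem) > 0) {
      dev <- sweep(mem, 2, cent[j, ], "-")
      within[j] <- mean(rowSums(dev^2))
      fsd[j, ] <- sqrt(colMeans(dev^2))
    }
  }
  list(shares = shares, within_var = within, feature_sd = fsd)
}

#' Lloyd's k-means algorithm (single run)
#'
#' Starts from k distinct data rows sampled uniformly under `seed`, then
#' alternates nearest-centroid assignment (squared Euclidean distance) and
#' centroid mean updates until the largest centroid displacement falls below
#' `tol` or `max_iter` iterations are reached. The objective
#' `sum_j sum_{i in C_j} ||x_i - c_j||^2` is non-increasing over iterations.
#' A cluster that runs empty during iteration is re-seeded deterministically
#' at the point farthest from its nearest centroid.
#'
#' @param fm a [feature_matrix()] (normally z-normalised).
#' @param k number of clusters, `1 <= k <= N`.
#' @param seed integer seed for the random start.
#' @param max_iter maximum number of Lloyd iterations (default 1000).
#' @param tol convergence threshold on the maximum centroid displacement
#'   (Euclidean, in normalised units; default 1e-6).
#' @param method distance evaluation path, see [assign_labels()].
#' @return a [centroid_set()] with `objective` set, plus attributes
#'   `iterations`, `objective_trace` (objective after each assignment) and
#'   `labels` (final assignment).
#' @export
lloyd <- function(fm, k, seed = 1L, max_iter = 1000L, tol = 1e-6,
                  method = c("fast", "naive")) {
  fm <- as_feature_matrix(fm)
  method <- match.arg(method)
  x <- fm$values
  n <- nrow(x)
  if (k <= 0) stop("k must be positive")
  if (k > n) stop("k = ", k, " exceeds the number of data points (", n, ")")
  set.seed(seed)
  cent <- x[sample.int(n, k), , drop = FALSE]
  trace <- numeric(0)
  iter <- 0L
  labels <- rep(1L, n)
  repeat {
    iter <- iter + 1L
    D <- sq_dist_to_centroids(x, cent, method)
    labels <- max.col(-D, ties.method = "first")
    # deterministic empty-cluster repair: farthest point from its nearest centroid
    guard <- 0L
    while (length(empty <- setdiff(seq_len(k), unique(labels))) > 0 &&
           guard < k) {
      guard <- guard + 1L
      dmin <- D[cbind(seq_len(n), labels)]
      far <- which.max(dmin)
      cent[empty[1], ] <- x[far, ]
      D <- sq_dist_to_centroids(x, cent, method)
      labels <- max.col(-D, ties.method = "first")
    }
    trace <- c(trace, sum(D[cbind(seq_len(n), labels)]))
    new_cent <- cent
    for (j in seq_len(k))
      new_cent[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    shift <- sqrt(max(rowSums((new_cent - cent)^2)))
    cent <- new_cent
    if (shift < tol || iter >= max_iter) break
  }
  D <- sq_dist_to_centroids(x, cent, method)
  labels <- max.col(-D, ties.method = "first")
  guard <- 0L
  while (length(empty <- setdiff(seq_len(k), unique(labels))) > 0 &&
         guard < k) {
    guard <- guard + 1L
    dmin <- D[cbind(seq_len(n), labels)]
    cent[empty[1], ] <- x[which.max(dmin), ]
    D <- sq_dist_to_centroids(x, cent, method)
    labels <- max.col(-D, ties.method = "first")
  }
  obj <- sum(D[cbind(seq_len(n), labels)])
  st <- cluster_stats(x, cent, labels)
  cs <- centroid_set(cent, st$shares, st$within_var, st$feature_sd,
                     norm = fm$norm, units = fm$units, objective = obj)
  attr(cs, "iterations") <- iter
  attr(cs, "objective_trace") <- c(trace, obj)
  attr(cs, "labels") <- labels
  cs
}

#' Restarted k-means
#'
#' Runs [lloyd()] from `n_restarts` different random starts (seeds
#' `base_seed, base_seed + 1, ...`) and returns the run with the smallest
#' objective; ties resolve to the lowest seed. Repeated restarts are
#' essential because a single Lloyd run only reaches a local minimum of the
#' variance objective.
#'
#' @param fm a [feature_matrix()] (normally z-normalised).
#' @param k number of clusters.
#' @param n_restarts number of independent starts (default 12).
#' @param base_seed seed of the first restart; restart r uses
#'   `base_seed + r - 1`.
#' @param ... further arguments passed to [lloyd()].
#' @return the best run's [centroid_set()] (attributes as in [lloyd()],
#'   plus `seed`, the winning seed).
#' @export
restarted_kmeans <- function(fm, k, n_restarts = 12L, base_seed = 1L, ...) {
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  best <- NULL
  best_seed <- NA_integer_
  for (r in seq_len(n_restarts)) {
    s <- base_seed + r - 1L
    cs <- lloyd(fm, k, seed = s, ...)
    if (is.null(best) || cs$objective < best$objective) {
      best <- cs
      best_seed <- s
    }
  }
  attr(best, "seed") <- best_seed
  best
}
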