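#' Agglomerative hierarchical clustering with Ward's criterion
#'
#' Greedy agglomeration starting from singletons, at each step merging the
#' two clusters whose fusion minimally increases the total within-cluster
#' variance. The increase for merging clusters with sizes n1, n2 and
#' centroids c1, c2 is `n1*n2/(n1+n2) * ||c1 - c2||^2` (squared Euclidean);
#' summed over all N-1 merges these joining costs telescope exactly to the
#' total variance `sum_i ||x_i - mean||^2`. The agglomeration itself is
#' delegated to [stats::hclust()] with Ward (ward.D2) linkage, whose heights
#' h relate to the joining cost as `cost = h^2 / 2`.
#'
#' This pre-scan is meant for moderate N (the distance matrix is O(N^2));
#' apply it to subsequences of a large data set to constrain the k range for
#' k-means, not to cluster the full data.
#'
#' @param fm a [feature_matrix()] (or bare numeric matrix).
#' @param max_n refuse data sets larger than this (default 20000); subsample
#'   instead.
#' @return an object of class `ward_dendrogram`: `merges` (data frame with
#'   hclust-coded member columns `a`, `b`, the `joining_cost` and the merged
#'   cluster `size`), `joining_costs` in merge order, `n`, and the underlying
#'   `hclust` object.
#' @export
ward_cluster <- function(fm, max_n = 20000L) {
  fm <- as_feature_matrix(fm)
  n <- nrow(fm$values)
  if (n < 2L) stop("need at least 2 points to cluster")
  if (n > max_n)
    stop("data set too large for the hierarchical pre-scan (", n, " > ",
         max_n, "); subsample, e.g. a few subsequences of ~5000 points")
  hc <- stats::hclust(stats::dist(fm$values), method = "ward.D2")
  costs <- hc$height^2 / 2
  size <- integer(n - 1L)
  for (j in seq_len(n - 1L)) {
    sa <- if (hc$merge[j, 1] < 0) 1L else size[hc$merge[j, 1]]
    sb <- if (hc$merge[j, 2] < 0) 1L else size[hc$merge[j, 2]]
    size[j] <- sa + sb
  }
  structure(list(
    merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                        joining_cost = costs, size = size),
    joining_costs = costs, n = n, hclust = hc),
    class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("Ward dendrogram: ", x$n, " points, ", x$n - 1L, " merges\n", sep = "")
  cat("  total joining cost (= total variance): ",
      format(sum(x$joining_costs)), "\n", sep = "")
  invisible(x)
}

#' Joining-cost curve of a Ward dendrogram
#'
#' Re-indexes the merge costs by the number of clusters: the entry at
#' `num_clusters = m` is the cost of going from m to m-1 clusters
#' (m = N..2). The differential cost at m is `cost(m) - cost(m+1)`
#' (NA for m = N). A pronounced jump when merging below some m suggests m
#' clusters; no monotonicity is guaranteed or assumed.
#'
#' @param d a `ward_dendrogram` from [ward_cluster()].
#' @return a data frame of class `cost_curve` with columns `num_clusters`
#'   (descending from N to 2), `cost` and `differential`.
#' @export
cost_curve <- function(d) {
  stopifnot(inherits(d, "ward_dendrogram"))
  m <- seq(d$n, 2L)                 # merge j goes from n-j+1 to n-j clusters
  cost <- d$joining_costs
  out <- data.frame(num_clusters = m, cost = cost,
                    differential = c(NA_real_, diff(cost)))
  class(out) <- c("cost_curve", "data.frame")
  out
}

#' Suggest a k range from a joining-cost curve
#'
#' Heuristic elbow rule: scanning k upward, the anchor is the smallest k
#' whose joining cost (cost of merging from k to k-1 clusters) exceeds
#' `factor` times the median of the next `window` costs at larger cluster
#' counts. The suggested range is the conservative `[2, anchor + margin]`.
#' If no cost stands out (noisy data without distinct cluster structure),
#' the configured fallback range is returned with a warning.
#'
#' The default `factor` reflects the two regimes the rule must separate:
#' unstructured data produces a smoothly accelerating cost curve whose
#' local window-median ratios stay below roughly 5 even at small k, while
#' merging across a genuine well-separated cluster boundary raises the
#' cost by an order of magnitude or more.
#'
#' @param curve a `cost_curve` from [cost_curve()].
#' @param window number of neighbouring costs forming the local reference
#'   (default 5); the curve must contain at least this many entries.
#' @param factor multiple of the local median that counts as a significant
#'   increase (default 8).
#' @param margin added above the anchor to widen the range (default 3).
#' @param fallback range returned when no elbow is found (default c(2, 50)).
#' @return integer vector `c(k_min, k_max)` with attribute `elbow` (the
#'   anchor k, or NA if the fallback was used).
#' @export
suggest_k_range <- function(curve, window = 5L, factor = 8, margin = 3L,
                            fallback = c(2L, 50L)) {
  stopifnot(inherits(curve, "cost_curve"))
  if (nrow(curve) < window)
    stop("cost curve shorter than the reference window")
  cost_at <- function(m) curve$cost[match(m, curve$num_clusters)]
  m_max <- max(curve$num_clusters)
  for (k in if (m_max - window >= 2L) 2:(m_max - window) else integer(0)) {
    ref <- cost_at((k + 1):(k + window))
    med <- stats::median(ref)
    if (is.finite(med) && med > 0 && cost_at(k) > factor * med) {
      out <- c(2L, k + margin)
      attr(out, "elbow") <- k
      return(out)
    }
  }
  warning("no distinct joining-cost increase found; returning fallback range [",
          fallback[1], ", ", fallback[2], "]")
  out <- as.integer(fallback)
  attr(out, "elbow") <- NA_integer_
  out
}
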