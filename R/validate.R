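#' Systematic leave-out resampling plan
#'
#' Builds data-set variations for stability analysis of sequentially
#' recorded data: instead of randomly subsampling points (which destroys the
#' temporal structure), a contiguous block of `round(N * fraction)` indices
#' is removed at `n_positions` equidistant cut positions; the remaining
#' indices are kept in their original order. Blocks near the end of the
#' sequence wrap around to the beginning so every mask keeps the same number
#' of points, and over all positions every index is kept at least once.
#'
#' @param n number of data points.
#' @param fraction fraction of the data to leave out, in (0, 1); the
#'   canonical values are 0.1, 0.2 and 0.5.
#' @param n_positions number of equidistant cut positions (default 50,
#'   i.e. every 2% of the sequence).
#' @return an object of class `leave_out_plan` with elements `fraction`,
#'   `n_positions`, `block_length` and `masks` (list of kept-index vectors).
#' @export
leave_out_plan <- function(n, fraction, n_positions = 50L) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  if (n_positions < 1L) stop("n_positions must be >= 1")
  len <- round(n * fraction)
  if (len < 1L) stop("n * fraction must be at least 1")
  masks <- vector("list", n_positions)
  for (p in seq_len(n_positions)) {
    start <- round((p - 1L) * n / n_positions)      # 0-based block start
    drop <- (start + seq_len(len) - 1L) %% n + 1L   # wraps at the end
    masks[[p]] <- setdiff(seq_len(n), drop)
  }
  structure(list(fraction = fraction, n_positions = as.integer(n_positions),
                 block_length = len, n = as.integer(n), masks = masks),
            class = "leave_out_plan")
}

#' @export
print.leave_out_plan <- function(x, ...) {
  cat("leave-out plan: drop ", x$block_length, "/", x$n, " points (",
      round(100 * x$fraction), "%) at ", x$n_positions,
      " equidistant positions\n", sep = "")
  invisible(x)
}

#' Distance between two centroid configurations
#'
#' Matches the centroids of two equal-cardinality sets one-to-one by the
#' Hungarian algorithm, minimising the sum of squared Euclidean centroid
#' distances, and returns that minimal sum normalised by the number of
#' centroids and the number of features (`/ (k * F)`), so that
#' configurations of different k or dimensionality are comparable. The
#' measure is a pseudometric: symmetric, zero iff the sets are equal up to
#' relabelling, and obeying the triangle inequality.
#'
#' @param a,b [centroid_set()] objects with equal k and F.
#' @return list with `matching` (integer vector: centroid j of `a` is
#'   matched to `matching[j]` of `b`) and `distance` (normalised matched
#'   squared distance).
#' @export
match_distance <- function(a, b) {
  stopifnot(inherits(a, "centroid_set"), inherits(b, "centroid_set"))
  k <- nrow(a$centroids)
  if (nrow(b$centroids) != k)
    stop("centroid sets have different cardinality (", k, " vs ",
         nrow(b$centroids), "); the distance is defined for equal k only")
  if (ncol(a$centroids) != ncol(b$centroids))
    stop("centroid sets live in different feature spaces")
  cost <- sq_dist_to_centroids(a$centroids, b$centroids, method = "naive")
  if (k == 1L) {
    matching <- 1L
  } else {
    matching <- solve_assignment(cost)
  }
  d <- sum(cost[cbind(seq_len(k), matching)]) / (k * ncol(a$centroids))
  list(matching = matching, distance = d)
}

#' Mean set of centroids and instability
#'
#' Given repeated clustering results (random restarts, or the same k fitted
#' on leave-out variations of the data), computes all pairwise
#' [match_distance()]s, identifies the *mean set* — the member with the
#' smallest mean distance to all the others — and takes that minimal mean
#' distance as the instability of the collection. The error of the mean is
#' reported as the standard deviation of the mean set's distances to the
#' others divided by the number of sets.
#'
#' @param sets list of at least two [centroid_set()]s with equal k and F.
#' @return an object of class `stability_report`: `pairwise` (symmetric
#'   distance matrix), `mean_set_index`, `mean_set` (the chosen
#'   [centroid_set()]), `instability` and `mean_error`.
#' @export
mean_set <- function(sets) {
  s <- length(sets)
  if (s < 2L) stop("need at least 2 centroid sets")
  pw <- matrix(0, s, s)
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      d <- match_distance(sets[[i]], sets[[j]])$distance
      pw[i, j] <- d
      pw[j, i] <- d
    }
  }
  row_means <- rowSums(pw) / (s - 1L)   # mean distance to the *other* sets
  idx <- which.min(row_means)           # which.min takes the lowest index on ties
  others <- pw[idx, -idx]
  structure(list(pairwise = pw, mean_set_index = idx,
                 mean_set = sets[[idx]], instability = row_means[idx],
                 mean_error = stats::sd(others) / s),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability over ", nrow(x$pairwise), " centroid sets: instability ",
      format(x$instability), " +/- ", format(x$mean_error),
      " (mean set: #", x$mean_set_index, ")\n", sep = "")
  invisible(x)
}

#' Per-cluster quality of a clustering
#'
#' Separation/compactness index per cluster: dense clusters have a small
#' within-cluster variance `inner_j` (mean squared Euclidean distance of the
#' members to their centroid), well-separated clusters have a large squared
#' distance `outer_j` to the nearest other centroid. The per-cluster quality
#' is the squared-units ratio `Q_j = outer_j / inner_j`, and the mean over
#' clusters scores the whole clustering. A zero-variance cluster with
#' positive separation yields `Q_j = Inf`; it is excluded from the mean with
#' a warning.
#'
#' @param fm the [feature_matrix()] the clustering refers to (the full
#'   analysis data, even when the centroids were fitted on a reduced set).
#' @param cs a [centroid_set()] with k >= 2.
#' @param labels optional pre-computed assignment (defaults to
#'   [assign_labels()] of `fm` to `cs`); every cluster must be non-empty.
#' @return an object of class `quality_report`: `per_cluster_q`, `mean_q`,
#'   `inner`, `outer`.
#' @export
cluster_quality <- function(fm, cs, labels = NULL) {
  fm <- as_feature_matrix(fm)
  stopifnot(inherits(cs, "centroid_set"))
  k <- nrow(cs$centroids)
  if (k < 2L) stop("quality needs at least 2 clusters (no outer distance for k = 1)")
  if (is.null(labels)) labels <- assign_labels(fm, cs)
  counts <- tabulate(labels, k)
  if (any(counts == 0))
    stop("empty cluster(s): ", paste(which(counts == 0), collapse = ", "))
  inner <- numeric(k)
  for (j in seq_len(k)) {
    dev <- sweep(fm$values[labels == j, , drop = FALSE], 2,
                 cs$centroids[j, ], "-")
    inner[j] <- mean(rowSums(dev^2))
  }
  cc <- sq_dist_to_centroids(cs$centroids, cs$centroids, method = "naive")
  diag(cc) <- Inf
  outer <- apply(cc, 1, min)
  q <- outer / inner
  if (any(!is.finite(q))) {
    warning("cluster(s) ", paste(which(!is.finite(q)), collapse = ", "),
            " have zero within-cluster variance; Q reported as Inf and ",
            "excluded from the mean")
  }
  structure(list(per_cluster_q = q, mean_q = mean(q[is.finite(q)]),
                 inner = inner, outer = outer),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("cluster quality: mean Q = ", format(x$mean_q), "\n  per cluster: ",
      paste(signif(x$per_cluster_q, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# deterministic seed derivation for the scan; stays far below 2^31
scan_seed <- function(base_seed, k, cond, slot) {
  base_seed + k * 1000000L + cond * 100000L + slot * 100L
}

#' Validation scan over cluster numbers and data-set conditions
#'
#' For every k in `k_range` the scan measures (a) within-condition
#' stability: the full data re-clustered from `n_full_runs` different random
#' starts, and each leave-out condition ([leave_out_plan()]) clustered once
#' per mask with [restarted_kmeans()]; (b) between-condition stability of
#' the per-condition mean sets; and (c) the quality of each condition's mean
#' set, always evaluated on the full data. [select_k()] is applied to the
#' finished report with default settings.
#'
#' The feature matrix is normalised once; leave-out subsets reuse the full
#' data's normalisation so centroids from all conditions live in one space.
#'
#' @param fm z-normalised [feature_matrix()] of the full analysis data.
#' @param k_range integer vector of cluster numbers to scan.
#' @param fractions leave-out fractions (default c(0.1, 0.2, 0.5)).
#' @param n_positions cut positions per fraction (default 50).
#' @param n_full_runs independent single Lloyd runs on the full data
#'   (default 10).
#' @param restarts restarts per leave-out clustering (default 12).
#' @param base_seed master seed; all run seeds derive deterministically from
#'   it, so the scan is fully reproducible.
#' @param verbose print progress per k.
#' @return an object of class `validation_report`: `k_range`, `conditions`,
#'   `settings`, per-k `results` (each with `within` stability reports per
#'   condition, `between` stability report, `quality` reports per condition
#'   and `mean_quality`), and `selected_k`.
#' @export
validation_scan <- function(fm, k_range, fractions = c(0.1, 0.2, 0.5),
                            n_positions = 50L, n_full_runs = 10L,
                            restarts = 12L, base_seed = 1L,
                            verbose = FALSE) {
  fm <- as_feature_matrix(fm)
  if (length(k_range) == 0) stop("k_range must be non-empty")
  n <- nrow(fm$values)
  conditions <- c("full", if (length(fractions))
    paste0("leaveout_", fractions))
  plans <- lapply(fractions, function(f) leave_out_plan(n, f, n_positions))
  results <- list()
  for (k in k_range) {
    within <- list()
    # condition 1: full data, repeated runs from different random starts
    # (each "run" is itself a restarted fit: a long k-means run re-selects
    # random start positions every time it converges)
    full_sets <- lapply(seq_len(n_full_runs), function(r)
      restarted_kmeans(fm, k, n_restarts = restarts,
                       base_seed = scan_seed(base_seed, k, 0L, r)))
    within[["full"]] <- mean_set(full_sets)
    # leave-out conditions: one restarted fit per mask
    for (ci in seq_along(plans)) {
      plan <- plans[[ci]]
      sets <- lapply(seq_along(plan$masks), function(mi)
        restarted_kmeans(fm_rows(fm, plan$masks[[mi]]), k,
                         n_restarts = restarts,
                         base_seed = scan_seed(base_seed, k, ci, mi)))
      within[[conditions[ci + 1L]]] <- mean_set(sets)
    }
    mean_sets <- lapply(within, `[[`, "mean_set")
    between <- if (length(mean_sets) >= 2L) mean_set(mean_sets)
               else within[[1L]]
    quality <- lapply(mean_sets, function(ms) cluster_quality(fm, ms))
    results[[as.character(k)]] <- list(
      within = within, between = between, quality = quality,
      mean_quality = mean(vapply(quality, `[[`, numeric(1), "mean_q")))
    if (verbose)
      message("k = ", k, ": between-condition instability ",
              signif(between$instability, 3), ", mean quality ",
              signif(results[[as.character(k)]]$mean_quality, 3))
  }
  report <- structure(list(k_range = as.integer(k_range),
                           conditions = conditions,
                           settings = list(fractions = fractions,
                                           n_positions = n_positions,
                                           n_full_runs = n_full_runs,
                                           restarts = restarts,
                                           base_seed = base_seed,
                                           n = n),
                           results = results, selected_k = NA_integer_),
                      class = "validation_report")
  report$selected_k <- tryCatch(select_k(report),
                                error = function(e) NA_integer_)
  report
}

#' Select the number of prototypes from a validation report
#'
#' Stability is a prerequisite, quality decides among the stable options:
#' a k is admissible when its between-condition instability is at most
#' `factor` times the smallest instability over the scanned range, or below
#' the absolute floor `abs_floor` (when the most stable k has essentially
#' zero instability, any other k whose instability is negligible on the
#' same absolute scale is equally stable; 0.003 is the level below which
#' instabilities on z-normalised data count as very small). A finite
#' `abs_cap` caps the threshold from above. Among the admissible k the one
#' with the highest mean quality of the condition mean sets wins, ties
#' going to the smaller k.
#'
#' @param report a `validation_report` from [validation_scan()].
#' @param factor instability multiple that still counts as stable
#'   (default 2).
#' @param abs_floor absolute instability below which every k counts as
#'   stable (default 0.003, in normalised units).
#' @param abs_cap absolute instability cap (default Inf: no cap).
#' @return the selected k (integer).
#' @export
select_k <- function(report, factor = 2, abs_floor = 0.003, abs_cap = Inf) {
  stopifnot(inherits(report, "validation_report"))
  ks <- report$k_range
  inst <- vapply(report$results, function(r) r$between$instability,
                 numeric(1))
  qual <- vapply(report$results, `[[`, numeric(1), "mean_quality")
  thr <- min(max(factor * min(inst), abs_floor), abs_cap)
  admissible <- inst <= thr
  if (!any(admissible))
    stop("no k is admissible under the stability rule; instabilities: ",
         paste(sprintf("k=%d: %.4g", ks, inst), collapse = ", "))
  cand <- which(admissible)
  best <- cand[order(-qual[cand], ks[cand])][1L]
  as.integer(ks[best])
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation scan over k = {", paste(x$k_range, collapse = ", "),
      "}, conditions: ", paste(x$conditions, collapse = ", "), "\n", sep = "")
  inst <- vapply(x$results, function(r) r$between$instability, numeric(1))
  qual <- vapply(x$results, `[[`, numeric(1), "mean_quality")
  print(data.frame(k = x$k_range, between_instability = signif(inst, 4),
                   mean_quality = signif(qual, 4), row.names = NULL))
  cat("selected k:", x$selected_k, "\n")
  invisible(x)
}
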