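#' Fit prototypical movement components
#'
#' The central fitting function: takes behavioural data (a 6-DOF
#' [trajectory6d()] or a ready-made [feature_matrix()]), prepares features
#' (smoothing and body-frame velocity extraction for trajectories,
#' z-normalisation unless already normalised), and estimates k prototypes
#' with [restarted_kmeans()]. When `k` is not given, it is chosen by the
#' full validation framework ([validation_scan()] + [select_k()]): stability
#' under random restarts and systematic leave-out resampling is a
#' prerequisite, quality decides among the stable cluster numbers.
#'
#' @param x a [trajectory6d()] or [feature_matrix()] (or bare numeric
#'   matrix) in physical units, or an already z-normalised feature matrix.
#' @param k number of prototypes; NULL (default) selects k via the
#'   validation scan over `k_range`.
#' @param k_range candidate cluster numbers for the scan (default 2:12).
#' @param restarts random restarts per k-means fit (default 12).
#' @param seed master seed for all randomness.
#' @param smooth for trajectory input: apply the zero-phase Butterworth
#'   smoother first (default TRUE).
#' @param scan_args further arguments passed to [validation_scan()] (e.g.
#'   `fractions`, `n_positions`, `verbose`).
#' @param ... further arguments passed to [restarted_kmeans()].
#' @return an object of class `prototypes`: the normalised-space
#'   [centroid_set()] (`centroids`), the renormalised physical-units
#'   prototypes (`prototypes`), the per-step `labels`, the `report` (NULL
#'   when k was given), the [cluster_quality()] of the fit, and bookkeeping
#'   (`norm`, `call`). Methods: [print()], [summary()], [coef()]
#'   (physical-units prototype matrix), [predict()] (labels for new data),
#'   [fitted()] (assigned prototype per step, physical units),
#'   [residuals()] (observed minus assigned prototype), [plot()]
#'   (star plots).
#' @examples
#' set.seed(1)
#' gm <- gaussian_mixture(default_artificial_spec())
#' fit <- prototypes(gm$features, k = 5, seed = 1)
#' fit
#' table(predict(fit, gm$features), gm$labels)
#' @export
prototypes <- function(x, k = NULL, k_range = 2:12, restarts = 12L,
                       seed = 1L, smooth = TRUE, scan_args = list(), ...) {
  cl <- match.call()
  if (inherits(x, "trajectory6d")) {
    if (smooth) x <- smooth_trajectory(x)
    x <- body_frame_velocities(x)
  }
  fm_raw <- as_feature_matrix(x)
  fm <- if (is.null(fm_raw$norm)) znormalize(fm_raw) else fm_raw
  report <- NULL
  if (is.null(k)) {
    report <- do.call(validation_scan,
                      c(list(fm = fm, k_range = k_range,
                             restarts = restarts, base_seed = seed),
                        scan_args))
    k <- report$selected_k
    if (is.na(k))
      stop("validation scan could not select k; inspect the report")
  }
  cs <- restarted_kmeans(fm, k, n_restarts = restarts, base_seed = seed, ...)
  labels <- attr(cs, "labels")
  qual <- if (k >= 2L) cluster_quality(fm, cs, labels) else NULL
  structure(list(centroids = cs, prototypes = renormalize_centroids(cs),
                 labels = labels, report = report, quality = qual,
                 norm = fm$norm, t = fm$t, dt = infer_dt(fm$t),
                 call = cl),
            class = "prototypes")
}

infer_dt <- function(t) {
  if (is.null(t) || length(t) < 2L) return(1)
  diff(t)[1]
}

#' @export
print.prototypes <- function(x, ...) {
  k <- nrow(x$centroids$centroids)
  cat("prototypical components: k = ", k, ", ",
      length(x$labels), " time steps\n", sep = "")
  if (!is.null(x$report))
    cat("  k selected by validation scan over k = {",
        paste(x$report$k_range, collapse = ", "), "}\n", sep = "")
  cat("  shares: ", paste(sprintf("%.1f%%", 100 * x$centroids$shares),
                          collapse = ", "), "\n", sep = "")
  if (!is.null(x$quality))
    cat("  mean quality: ", format(signif(x$quality$mean_q, 4)), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.prototypes <- function(object, ...) {
  out <- list(k = nrow(object$centroids$centroids),
              prototypes = coef(object),
              shares = object$centroids$shares,
              quality = object$quality,
              selected_by_scan = !is.null(object$report),
              segments = segment(object))
  class(out) <- "summary.prototypes"
  out
}

#' @export
print.summary.prototypes <- function(x, ...) {
  cat("prototypes in physical units (rows = prototypes):\n")
  print(round(x$prototypes, 3))
  cat("\nshares:", paste(sprintf("%.1f%%", 100 * x$shares),
                         collapse = ", "), "\n")
  if (!is.null(x$quality)) {
    cat("per-cluster quality: ",
        paste(signif(x$quality$per_cluster_q, 3), collapse = ", "),
        " (mean ", signif(x$quality$mean_q, 4), ")\n", sep = "")
  }
  cat("segmentation: ", nrow(x$segments$segments),
      " prototypical movements, median duration ",
      stats::median(x$segments$segments$duration_ms), " ms\n", sep = "")
  invisible(x)
}

#' @export
coef.prototypes <- function(object, ...) object$prototypes$centroids

#' Assign new data to fitted prototypes
#'
#' @param object a `prototypes` fit.
#' @param newdata a [trajectory6d()] or [feature_matrix()] in physical
#'   units (it is normalised with the training parameters), or an already
#'   normalised feature matrix. Missing `newdata` returns the training
#'   labels.
#' @param ... unused.
#' @return integer vector of prototype labels.
#' @export
predict.prototypes <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  if (inherits(newdata, "trajectory6d"))
    newdata <- body_frame_velocities(smooth_trajectory(newdata))
  fm <- as_feature_matrix(newdata)
  if (is.null(fm$norm)) fm <- znormalize(fm, params = object$norm)
  assign_labels(fm, object$centroids)
}

#' @export
fitted.prototypes <- function(object, ...) {
  object$prototypes$centroids[object$labels, , drop = FALSE]
}

#' Residuals of a prototype fit
#'
#' Observed physical-units feature values minus the assigned prototype's
#' values: what the reduction of behaviour to k prototypes leaves
#' unexplained at each time step.
#'
#' @param object a `prototypes` fit.
#' @param fm the feature matrix the fit was computed on (physical units);
#'   required because the fit does not store the data.
#' @param ... unused.
#' @return numeric matrix, rows = time steps.
#' @export
residuals.prototypes <- function(object, fm, ...) {
  fm <- as_feature_matrix(fm)
  vals <- if (!is.null(fm$norm)) renormalize_features(fm)$values else
    fm$values
  if (nrow(vals) != length(object$labels))
    stop("fm does not match the fitted data (", nrow(vals), " rows vs ",
         length(object$labels), " labels)")
  vals - fitted(object)
}

#' @export
plot.prototypes <- function(x, path = NULL, ...) {
  star_plot(x$prototypes, path = path, ...)
  invisible(x)
}

#' Segment a prototype fit into prototypical movements
#'
#' @param object a `prototypes` fit.
#' @param ... passed to [segment_labels()].
#' @return a [segment_labels()] `segment_list` of the training labels.
#' @export
segment <- function(object, ...) UseMethod("segment")

#' @export
segment.prototypes <- function(object, ...) {
  t0 <- if (!is.null(object$t)) object$t[1] else 0
  segment_labels(object$labels, dt = object$dt, t0 = t0, ...)
}
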