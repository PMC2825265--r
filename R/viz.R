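# Diagnostic graphics. All plotting is side-effect only: inputs are never
# mutated and no numeric result depends on these functions.

open_device <- function(path, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width * 100,
                              height = height * 100, res = 100),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported plot format '", ext, "' (use png, svg or pdf)"))
}

# ray direction for feature f of F: equi-angular across the upper half-plane
ray_angle <- function(f, n_features) pi * (f - 0.5) / n_features

#' Modified star plots of a centroid set
#'
#' One panel per centroid. Each feature owns one ray direction; the F
#' positive directions are spread equi-angularly over the upper half-plane,
#' and a negative feature value is drawn on the same ray with opposite
#' orientation (lower half-plane). The marker sits at radius |value|; an
#' error bar along the ray shows the per-cluster standard deviation of the
#' feature; rays are coloured per feature, and no line connects the centre
#' to the marker (the error bars stay visible). Panel titles show the share
#' of data assigned to the centroid.
#'
#' @param cs a [centroid_set()]; `feature_sd` is used for the error bars
#'   when present.
#' @param path output file (png/svg/pdf by extension), or NULL to draw on
#'   the current device.
#' @param labels optional panel titles (default: centroid index and share).
#' @param max_radius fixed radial scale; default: common scale over all
#'   centroids including error bars.
#' @return invisibly, the per-feature colours used.
#' @export
star_plot <- function(cs, path = NULL, labels = NULL, max_radius = NULL) {
  stopifnot(inherits(cs, "centroid_set"))
  k <- nrow(cs$centroids)
  f <- ncol(cs$centroids)
  sd_mat <- if (!is.null(cs$feature_sd)) cs$feature_sd else
    matrix(0, k, f)
  if (is.null(max_radius))
    max_radius <- max(abs(cs$centroids) + sd_mat, 1e-12)
  cols <- grDevices::hcl.colors(f, "Dark 3")
  if (is.null(labels))
    labels <- sprintf("prototype %d (%.0f%%)", seq_len(k), 100 * cs$shares)
  if (!is.null(path)) {
    open_device(path, width = 2.6 * min(k, 3), height = 2.8 * ceiling(k / 3))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(ceiling(k / 3), min(k, 3)),
                      mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  ang <- ray_angle(seq_len(f), f)
  for (j in seq_len(k)) {
    graphics::plot(NA, xlim = c(-1.1, 1.1) * max_radius,
                   ylim = c(-1.1, 1.1) * max_radius, asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = labels[j])
    graphics::abline(h = 0, col = "grey85")
    graphics::symbols(0, 0, circles = max_radius, inches = FALSE,
                      add = TRUE, fg = "grey85")
    v <- cs$centroids[j, ]
    a <- ifelse(v >= 0, ang, ang + pi)   # negative values: opposite orientation
    r <- abs(v)
    s <- sd_mat[j, ]
    graphics::segments((r - s) * cos(a), (r - s) * sin(a),
                       (r + s) * cos(a), (r + s) * sin(a),
                       col = cols, lwd = 2)
    graphics::points(r * cos(a), r * sin(a), pch = 19, col = cols,
                     cex = 1.1)
  }
  invisible(cols)
}

#' Diagnostic plots of a validation report
#'
#' Writes four figures into a directory: within-condition instability vs k
#' (one curve per data condition, with error bars), between-condition
#' instability vs k, mean quality vs k per condition, and the per-cluster
#' quality bar chart of the full-data mean set at the selected k.
#'
#' @param report a `validation_report` from [validation_scan()].
#' @param out_dir output directory (created if missing).
#' @param format "png", "svg" or "pdf".
#' @return character vector of the files written, invisibly.
#' @export
report_plots <- function(report, out_dir, format = "png") {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ks <- report$k_range
  conds <- report$conditions
  files <- character(0)
  pfile <- function(name) file.path(out_dir, paste0(name, ".", format))

  inst <- sapply(conds, function(cn) vapply(report$results, function(r)
    r$within[[cn]]$instability, numeric(1)))
  err <- sapply(conds, function(cn) vapply(report$results, function(r)
    r$within[[cn]]$mean_error, numeric(1)))
  cols <- grDevices::hcl.colors(max(length(conds), 2), "Dark 3")

  f <- pfile("instability_within")
  open_device(f, 6, 5)
  graphics::matplot(ks, inst, type = "b", pch = 19, lty = 1, col = cols,
                    xlab = "number of clusters k",
                    ylab = "instability (within condition)", xaxt = "n")
  graphics::axis(1, at = ks)
  for (i in seq_along(conds))
    graphics::segments(ks, inst[, i] - err[, i], ks, inst[, i] + err[, i],
                       col = cols[i], lwd = 2)
  graphics::legend("topleft", legend = conds, col = cols, pch = 19,
                   bty = "n")
  grDevices::dev.off()
  files <- c(files, f)

  binst <- vapply(report$results, function(r) r$between$instability,
                  numeric(1))
  f <- pfile("instability_between")
  open_device(f, 6, 5)
  graphics::plot(ks, binst, type = "b", pch = 19, xaxt = "n",
                 xlab = "number of clusters k",
                 ylab = "instability (between conditions)")
  graphics::axis(1, at = ks)
  grDevices::dev.off()
  files <- c(files, f)

  qual <- sapply(conds, function(cn) vapply(report$results, function(r)
    r$quality[[cn]]$mean_q, numeric(1)))
  f <- pfile("quality_mean")
  open_device(f, 6, 5)
  graphics::matplot(ks, qual, type = "b", pch = 19, lty = 1, col = cols,
                    xlab = "number of clusters k",
                    ylab = "mean quality of mean set", xaxt = "n")
  graphics::axis(1, at = ks)
  graphics::legend("topright", legend = conds, col = cols, pch = 19,
                   bty = "n")
  grDevices::dev.off()
  files <- c(files, f)

  ksel <- report$selected_k
  if (!is.na(ksel) && as.character(ksel) %in% names(report$results)) {
    q <- report$results[[as.character(ksel)]]$quality[["full"]]
    f <- pfile("quality_per_cluster")
    open_device(f, 6, 5)
    graphics::barplot(q$per_cluster_q,
                      names.arg = seq_along(q$per_cluster_q),
                      xlab = "cluster", ylab = "quality Q",
                      main = paste0("per-cluster quality, k = ", ksel))
    graphics::abline(h = q$mean_q, lty = 2)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

#' @export
plot.ward_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, labels = FALSE, hang = -1,
                 main = "Ward dendrogram", xlab = "", sub = "", ...)
  invisible(x)
}

#' @export
plot.cost_curve <- function(x, max_k = 20L, ...) {
  sub <- x[x$num_clusters <= max_k, ]
  graphics::plot(sub$num_clusters, sub$cost, type = "b", pch = 19,
                 xlab = "number of clusters", ylab = "joining cost", ...)
  invisible(x)
}
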