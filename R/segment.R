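#' Segment a label sequence into prototypical movements
#'
#' Collapses a per-time-step prototype label sequence into its maximal runs
#' of constant label. Each run is one prototypical movement; its duration is
#' the run length times the sampling step. The segments tile the sequence
#' exactly: no gaps, no overlaps, adjacent segments always differ in label.
#'
#' @param labels integer (or factor/character) label sequence, one per time
#'   step.
#' @param dt sampling step in ms (default 1).
#' @param t0 time stamp of the first step (default 0 ms).
#' @return an object of class `segment_list`: data frame `segments` with
#'   columns `label`, `start_ms`, `end_ms`, `duration_ms`, plus `n_steps`
#'   and `dt`.
#' @export
segment_labels <- function(labels, dt = 1, t0 = 0) {
  if (length(labels) == 0) stop("label sequence must be non-empty")
  r <- rle(as.vector(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  seg <- data.frame(label = r$values,
                    start_ms = t0 + starts * dt,
                    end_ms = t0 + ends * dt,
                    duration_ms = r$lengths * dt)
  structure(list(segments = seg, n_steps = length(labels), dt = dt),
            class = "segment_list")
}

#' @export
print.segment_list <- function(x, ...) {
  cat("segmentation: ", nrow(x$segments), " prototypical movements over ",
      x$n_steps * x$dt, " ms\n", sep = "")
  cat("  median duration: ", stats::median(x$segments$duration_ms),
      " ms\n", sep = "")
  invisible(x)
}

#' Per-group duration statistics of prototypical movements
#'
#' Summarises segment durations per behavioural group (e.g. saccade vs
#' intersaccade) after mapping each prototype label to its group.
#'
#' @param sl a [segment_list()].
#' @param group_map named vector mapping every occurring label to a group
#'   name (e.g. the output of [classify_prototypes()]).
#' @param threshold duration threshold in ms for the exceedance fraction
#'   (default 20).
#' @return data frame with one row per group: `group`, `n`, `mean_ms`,
#'   `median_ms`, `sd_ms`, `frac_over` (fraction of segments longer than
#'   `threshold`).
#' @export
duration_stats <- function(sl, group_map, threshold = 20) {
  stopifnot(inherits(sl, "segment_list"))
  lab <- as.character(sl$segments$label)
  unmapped <- setdiff(unique(lab), names(group_map))
  if (length(unmapped) > 0)
    stop("unmapped label(s): ", paste(unmapped, collapse = ", "))
  grp <- unname(group_map[lab])
  out <- lapply(split(sl$segments$duration_ms, grp), function(d)
    data.frame(n = length(d), mean_ms = mean(d),
               median_ms = stats::median(d),
               sd_ms = if (length(d) > 1) stats::sd(d) else 0,
               frac_over = mean(d > threshold)))
  res <- do.call(rbind, out)
  cbind(group = rownames(res), res, row.names = NULL)
}

#' Classify prototypes as rotational or translational
#'
#' Labels a velocity prototype "rotational" when its largest absolute
#' normalised rotational component exceeds its largest absolute normalised
#' translational component by `factor`, and "translational" otherwise. This
#' reproduces the saccade/intersaccade split of saccadic flight: saccade
#' prototypes are dominated by yaw (plus coupled roll/pitch) even though
#' they also carry forward translation.
#'
#' The rule operates in normalised feature space. A centroid set still in
#' normalised space (with `norm` attached) is used directly; a renormalised
#' set (physical units) needs the normalisation parameters via `norm`.
#'
#' @param cs a [centroid_set()] over the six velocity features.
#' @param factor dominance factor (default 1: plain comparison).
#' @param norm normalisation parameters for a physical-units set.
#' @return named character vector: centroid index (as character) ->
#'   `"rotational"` or `"translational"`.
#' @export
classify_prototypes <- function(cs, factor = 1, norm = cs$norm) {
  stopifnot(inherits(cs, "centroid_set"))
  rot_cols <- velocity_columns(cs)$rotational
  trans_cols <- velocity_columns(cs)$translational
  z <- cs$centroids
  if (is.null(cs$norm)) {
    if (is.null(norm))
      stop("centroid set is in physical units but carries no normalisation ",
           "parameters; pass norm = list(mean, sd)")
    norm <- validate_norm(norm, ncol(z))
    z <- sweep(sweep(z, 2, norm$mean, "-"), 2, norm$sd, "/")
  }
  rot <- apply(abs(z[, rot_cols, drop = FALSE]), 1, max)
  trans <- apply(abs(z[, trans_cols, drop = FALSE]), 1, max)
  out <- ifelse(rot > factor * trans, "rotational", "translational")
  names(out) <- as.character(seq_len(nrow(z)))
  out
}

# locate translational / rotational velocity features by unit, falling back
# to the canonical feature names
velocity_columns <- function(cs) {
  f <- ncol(cs$centroids)
  if (!is.null(cs$units) && length(cs$units) == f &&
      any(cs$units == "m/s") && any(cs$units == "deg/ms")) {
    return(list(translational = which(cs$units == "m/s"),
                rotational = which(cs$units == "deg/ms")))
  }
  nm <- colnames(cs$centroids)
  trans <- match(c("forward", "sideward", "upward"), nm)
  rot <- match(c("yaw_vel", "pitch_vel", "roll_vel"), nm)
  if (anyNA(trans) || anyNA(rot))
    stop("centroid set does not look like six-velocity prototypes ",
         "(units m/s and deg/ms, or canonical feature names, not found); ",
         "supply a custom classification rule")
  list(translational = trans, rotational = rot)
}

#' Write a segment list to TSV
#'
#' Columns `label`, `start_ms`, `end_ms`, `duration_ms`, tab-separated with
#' a header row.
#'
#' @param sl a [segment_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(sl, path) {
  stopifnot(inherits(sl, "segment_list"))
  utils::write.table(sl$segments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
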