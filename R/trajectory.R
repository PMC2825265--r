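#' Construct a 6-DOF trajectory
#'
#' A `trajectory6d` holds a time-stamped rigid-body trajectory: 3-D position in
#' the world frame and 3-D orientation as Tait-Bryan angles (yaw, pitch, roll;
#' intrinsic Z-Y'-X'' composition). Internal units are fixed: time in
#' milliseconds, position in metres, angles in degrees. Time stamps must be
#' strictly increasing with a constant step `dt`.
#'
#' @param t numeric vector of time stamps in ms, strictly increasing, fixed step.
#' @param pos numeric T x 3 matrix of positions (x, y, z) in metres.
#' @param ori numeric T x 3 matrix of angles (yaw, pitch, roll) in degrees.
#' @return an object of class `trajectory6d` with elements `t`, `pos`, `ori`
#'   and the sampling step `dt` (ms).
#' @examples
#' tr <- trajectory6d(t = 0:9, pos = cbind(0:9 * 0.001, 0, 0),
#'                    ori = matrix(0, 10, 3))
#' tr$dt
#' @export
trajectory6d <- function(t, pos, ori) {
  t <- as.numeric(t)
  pos <- as.matrix(pos)
  ori <- as.matrix(ori)
  n <- length(t)
  if (n < 2L)
    stop("trajectory must contain at least 2 samples, got ", n)
  if (nrow(pos) != n || nrow(ori) != n)
    stop("t, pos and ori must have the same number of rows")
  if (ncol(pos) != 3L || ncol(ori) != 3L)
    stop("pos and ori must each have 3 columns")
  if (!all(is.finite(t)) || !all(is.finite(pos)) || !all(is.finite(ori)))
    stop("trajectory values must be finite")
  dts <- diff(t)
  if (any(dts <= 0))
    stop("time stamps must be strictly increasing (first violation at index ",
         which(dts <= 0)[1] + 1L, ")")
  dt <- dts[1]
  bad <- which(abs(dts - dt) > 1e-9 * max(abs(dt), 1))
  if (length(bad) > 0)
    stop("non-uniform sampling: dt changes from ", dt, " to ", dts[bad[1]],
         " ms at index ", bad[1] + 1L)
  colnames(pos) <- c("x", "y", "z")
  colnames(ori) <- c("yaw", "pitch", "roll")
  structure(list(t = t, pos = pos, ori = ori, dt = dt),
            class = "trajectory6d")
}

#' @export
print.trajectory6d <- function(x, ...) {
  cat("6-DOF trajectory: ", length(x$t), " samples, dt = ", x$dt,
      " ms (", round((length(x$t) - 1) * x$dt / 1000, 3), " s)\n", sep = "")
  cat("  position range [m]: x ",
      paste(signif(range(x$pos[, 1]), 3), collapse = " .. "), ", y ",
      paste(signif(range(x$pos[, 2]), 3), collapse = " .. "), ", z ",
      paste(signif(range(x$pos[, 3]), 3), collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' @export
length.trajectory6d <- function(x) length(x$t)

default_dialect <- function() {
  list(cols = c(t = "t", x = "x", y = "y", z = "z",
                yaw = "yaw", pitch = "pitch", roll = "roll"),
       time_unit = "ms",    # "ms" or "s"
       length_unit = "m",   # "m", "cm" or "mm"
       angle_unit = "deg")  # "deg" or "rad"
}

unit_factor <- function(unit, table, what) {
  if (!unit %in% names(table))
    stop("unsupported ", what, " unit '", unit, "'")
  table[[unit]]
}

#' Read a 6-DOF trajectory from CSV
#'
#' Reads a comma-separated file with a header row into a [trajectory6d()].
#' The default dialect expects columns `t,x,y,z,yaw,pitch,roll` in ms, metres
#' and degrees; `dialect` can remap column names and declare source units,
#' which are converted to the package's internal units on read.
#'
#' Readers reject invalid files (missing columns, non-uniform sampling)
#' rather than repairing them.
#'
#' @param path CSV file path.
#' @param dialect list with elements `cols` (named character vector mapping the
#'   canonical names `t,x,y,z,yaw,pitch,roll` to file column names),
#'   `time_unit` ("ms" or "s"), `length_unit` ("m", "cm", "mm") and
#'   `angle_unit` ("deg" or "rad"). Missing elements fall back to defaults.
#' @return a [trajectory6d()].
#' @seealso [write_trajectory()]
#' @export
read_trajectory <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::modifyList(default_dialect(), dialect)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(d$cols), names(df))
  if (length(missing) > 0)
    stop("trajectory file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  tf <- unit_factor(d$time_unit, list(ms = 1, s = 1000), "time")
  lf <- unit_factor(d$length_unit, list(m = 1, cm = 0.01, mm = 0.001), "length")
  af <- unit_factor(d$angle_unit, list(deg = 1, rad = 180 / pi), "angle")
  trajectory6d(
    t = df[[d$cols[["t"]]]] * tf,
    pos = cbind(df[[d$cols[["x"]]]], df[[d$cols[["y"]]]],
                df[[d$cols[["z"]]]]) * lf,
    ori = cbind(df[[d$cols[["yaw"]]]], df[[d$cols[["pitch"]]]],
                df[[d$cols[["roll"]]]]) * af)
}

#' Write a 6-DOF trajectory to CSV
#'
#' Writes the default dialect: header `t,x,y,z,yaw,pitch,roll`, comma
#' separator, '.' decimal, internal units (ms, m, deg). Round-trips through
#' [read_trajectory()] losslessly to full double precision.
#'
#' @param traj a [trajectory6d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory6d"))
  df <- data.frame(t = traj$t,
                   x = traj$pos[, 1], y = traj$pos[, 2], z = traj$pos[, 3],
                   yaw = traj$ori[, 1], pitch = traj$ori[, 2],
                   roll = traj$ori[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
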