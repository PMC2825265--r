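#' Construct a feature matrix
#'
#' A `feature_matrix` is a T x F numeric matrix of per-time-step feature
#' values with unique feature names, unit strings, optionally the time stamps
#' of the rows, and optionally the normalisation parameters (per-feature mean
#' and standard deviation) if the values are z-normalised.
#'
#' @param values numeric matrix, rows = time steps, columns = features.
#' @param names character vector of unique feature names (defaults to
#'   existing column names).
#' @param units character vector of unit strings, one per feature.
#' @param t optional numeric vector of row time stamps (ms).
#' @param norm optional list with numeric elements `mean` and `sd`
#'   (per feature, `sd` strictly positive): the parameters that were used to
#'   z-normalise `values`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, names = colnames(values),
                           units = rep("", ncol(values)), t = NULL,
                           norm = NULL) {
  values <- as.matrix(values)
  if (is.null(names)) names <- paste0("f", seq_len(ncol(values)))
  names <- as.character(names)
  if (length(names) != ncol(values))
    stop("need one name per feature column")
  if (anyDuplicated(names))
    stop("feature names must be unique")
  if (length(units) != ncol(values))
    stop("need one unit string per feature column")
  if (!all(is.finite(values)))
    stop("feature values must be finite (no NaN/Inf)")
  if (!is.null(t) && length(t) != nrow(values))
    stop("t must have one entry per row")
  if (!is.null(norm)) norm <- validate_norm(norm, ncol(values))
  colnames(values) <- names
  structure(list(values = values, units = as.character(units), t = t,
                 norm = norm),
            class = "feature_matrix")
}

validate_norm <- function(norm, f) {
  if (!is.list(norm) || is.null(norm$mean) || is.null(norm$sd))
    stop("norm must be a list with elements mean and sd")
  if (length(norm$mean) != f || length(norm$sd) != f)
    stop("norm parameters must have one entry per feature")
  if (any(norm$sd <= 0))
    stop("norm sd values must be strictly positive")
  list(mean = as.numeric(norm$mean), sd = as.numeric(norm$sd))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature matrix: ", nrow(x$values), " time steps x ", ncol(x$values),
      " features\n", sep = "")
  lab <- paste0(colnames(x$values),
                ifelse(nzchar(x$units), paste0(" [", x$units, "]"), ""))
  cat("  features:", paste(lab, collapse = ", "), "\n")
  if (!is.null(x$norm)) cat("  z-normalised (normalisation parameters attached)\n")
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# accept a feature_matrix or a bare numeric matrix wherever features go in
as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) return(x)
  if (is.matrix(x) && is.numeric(x)) return(feature_matrix(x))
  if (is.data.frame(x)) return(feature_matrix(as.matrix(x)))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a feature matrix")
}

# subset rows, keeping metadata
fm_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], colnames(fm$values),
                 fm$units, if (!is.null(fm$t)) fm$t[idx], fm$norm)
}

#' Write / read a feature matrix (TSV + JSON sidecar)
#'
#' The values go to a tab-separated file with a header row (plus a leading
#' `t` column when time stamps are present); units and normalisation
#' parameters go to a JSON sidecar at `<path>.json`. The pair round-trips
#' losslessly to double precision.
#'
#' @param fm a [feature_matrix()].
#' @param path TSV file path.
#' @return `write_features`: `path` invisibly; `read_features`: a
#'   [feature_matrix()].
#' @export
write_features <- function(fm, path) {
  fm <- as_feature_matrix(fm)
  df <- as.data.frame(fm$values)
  if (!is.null(fm$t)) df <- cbind(t = fm$t, df)
  con <- file(path, "w")
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  side <- list(names = colnames(fm$values), units = fm$units,
               has_time = !is.null(fm$t))
  if (!is.null(fm$norm)) side$norm <- fm$norm
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(names = setdiff(names(df), "t"),
         units = rep("", length(setdiff(names(df), "t"))),
         has_time = "t" %in% names(df))
  }
  t <- if (isTRUE(side$has_time)) df[["t"]] else NULL
  vals <- as.matrix(df[, side$names, drop = FALSE])
  feature_matrix(vals, side$names, side$units, t,
                 if (!is.null(side$norm)) side$norm)
}
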