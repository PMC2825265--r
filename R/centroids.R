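#' Construct a centroid set
#'
#' A `centroid_set` holds k cluster centroids in F-dimensional feature space
#' together with the fraction of the data assigned to each centroid, the
#' within-cluster variance (mean squared Euclidean distance of members to
#' their centroid), the per-cluster standard deviation of each feature among
#' members, and, when the centroids live in z-normalised space, the
#' normalisation parameters needed to express them in physical units again
#' (see [renormalize_centroids()]).
#'
#' @param centroids numeric k x F matrix.
#' @param shares numeric vector of k assignment fractions, summing to 1.
#' @param within_var numeric vector of k within-cluster variances (>= 0).
#' @param feature_sd optional numeric k x F matrix of per-cluster feature
#'   standard deviations.
#' @param norm optional normalisation parameters (list with `mean`, `sd`).
#' @param units optional character vector of feature unit strings.
#' @param objective optional k-means objective value of the producing run.
#' @return an object of class `centroid_set`.
#' @export
centroid_set <- function(centroids, shares, within_var,
                         feature_sd = NULL, norm = NULL, units = NULL,
                         objective = NULL) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 1L) stop("a centroid set needs k >= 1 centroids")
  shares <- as.numeric(shares)
  within_var <- as.numeric(within_var)
  if (length(shares) != k || length(within_var) != k)
    stop("shares and within_var must have one entry per centroid")
  if (abs(sum(shares) - 1) > 1e-9)
    stop("assignment shares must sum to 1 (got ", format(sum(shares)), ")")
  if (any(shares < 0)) stop("assignment shares must be non-negative")
  if (any(within_var < -1e-12)) stop("within-cluster variances must be >= 0")
  within_var <- pmax(within_var, 0)
  if (!is.null(feature_sd)) {
    feature_sd <- as.matrix(feature_sd)
    if (!all(dim(feature_sd) == dim(centroids)))
      stop("feature_sd must match the centroid matrix dimensions")
  }
  if (!is.null(norm)) norm <- validate_norm(norm, ncol(centroids))
  if (!is.null(units) && length(units) != ncol(centroids))
    stop("need one unit string per feature")
  structure(list(centroids = centroids, shares = shares,
                 within_var = within_var, feature_sd = feature_sd,
                 norm = norm, units = units, objective = objective),
            class = "centroid_set")
}

#' @export
print.centroid_set <- function(x, digits = 3, ...) {
  cat("centroid set: k = ", nrow(x$centroids), " in ", ncol(x$centroids),
      "-D feature space", if (!is.null(x$norm)) " (normalised units)",
      "\n", sep = "")
  tab <- cbind(round(x$centroids, digits),
               share = round(x$shares, digits),
               within_var = signif(x$within_var, digits))
  rownames(tab) <- paste0("c", seq_len(nrow(tab)))
  print(tab)
  if (!is.null(x$objective))
    cat("k-means objective:", format(x$objective), "\n")
  invisible(x)
}

n_clusters <- function(cs) nrow(cs$centroids)

#' Write / read a centroid set (JSON)
#'
#' Self-describing JSON serialisation of a [centroid_set()]; numbers are
#' written at full double precision so the pair round-trips losslessly.
#' Reading re-validates all invariants and rejects inconsistent files.
#'
#' @param cs a [centroid_set()].
#' @param path JSON file path.
#' @return `write_centroids`: `path` invisibly; `read_centroids`: a
#'   [centroid_set()].
#' @export
write_centroids <- function(cs, path) {
  stopifnot(inherits(cs, "centroid_set"))
  jsonlite::write_json(cs_to_list(cs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse centroid file ",
                                           path, ": ", conditionMessage(e)))
  cs_from_list(obj, what = paste("centroid file", path))
}

cs_to_list <- function(cs) {
  obj <- list(k = nrow(cs$centroids), n_features = ncol(cs$centroids),
              feature_names = colnames(cs$centroids),
              centroids = apply(cs$centroids, 1, as.numeric,
                                simplify = FALSE),
              shares = cs$shares, within_var = cs$within_var)
  if (!is.null(cs$feature_sd))
    obj$feature_sd <- apply(cs$feature_sd, 1, as.numeric, simplify = FALSE)
  if (!is.null(cs$norm)) obj$norm <- cs$norm
  if (!is.null(cs$units)) obj$units <- cs$units
  if (!is.null(cs$objective)) obj$objective <- cs$objective
  obj
}

cs_from_list <- function(obj, what = "centroid object") {
  for (need in c("centroids", "shares", "within_var"))
    if (is.null(obj[[need]])) stop(what, " lacks field '", need, "'")
  cent <- obj$centroids
  if (is.list(cent)) cent <- do.call(rbind, lapply(cent, unlist))
  cent <- matrix(as.numeric(cent), nrow = length(obj$shares))
  fsd <- obj$feature_sd
  if (is.list(fsd)) fsd <- do.call(rbind, lapply(fsd, unlist))
  if (!is.null(fsd)) fsd <- matrix(as.numeric(fsd), nrow = nrow(cent))
  if (!is.null(obj$feature_names) && length(obj$feature_names) == ncol(cent))
    colnames(cent) <- obj$feature_names
  centroid_set(cent, obj$shares, obj$within_var, fsd,
               norm = obj$norm, units = obj$units, objective = obj$objective)
}
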