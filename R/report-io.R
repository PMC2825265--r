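# JSON (de)serialisation of validation reports. Per-run centroid sets are
# not retained (only their pairwise distances and the mean sets), which
# keeps reports small while everything the selection rule and the plots
# need round-trips losslessly.

stab_to_list <- function(sr) {
  list(pairwise = apply(sr$pairwise, 1, as.numeric, simplify = FALSE),
       mean_set_index = sr$mean_set_index,
       mean_set = cs_to_list(sr$mean_set),
       instability = sr$instability, mean_error = sr$mean_error)
}

stab_from_list <- function(obj) {
  pw <- obj$pairwise
  if (is.list(pw)) pw <- do.call(rbind, lapply(pw, unlist))
  structure(list(pairwise = matrix(as.numeric(pw), nrow = nrow(pw)),
                 mean_set_index = as.integer(obj$mean_set_index),
                 mean_set = cs_from_list(obj$mean_set),
                 instability = obj$instability,
                 mean_error = obj$mean_error),
            class = "stability_report")
}

qual_to_list <- function(qr) {
  list(per_cluster_q = qr$per_cluster_q, mean_q = qr$mean_q,
       inner = qr$inner, outer = qr$outer)
}

qual_from_list <- function(obj) {
  structure(list(per_cluster_q = as.numeric(obj$per_cluster_q),
                 mean_q = obj$mean_q, inner = as.numeric(obj$inner),
                 outer = as.numeric(obj$outer)),
            class = "quality_report")
}

#' Write / read a validation report (JSON)
#'
#' Serialises a `validation_report` from [validation_scan()] to JSON and
#' back. Infinite per-cluster quality values survive the round trip (JSON
#' has no Inf; they are encoded as strings).
#'
#' @param report a `validation_report`.
#' @param path JSON file path.
#' @return `write_report`: `path` invisibly; `read_report`: a
#'   `validation_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  obj <- list(
    k_range = report$k_range, conditions = report$conditions,
    settings = report$settings, selected_k = report$selected_k,
    results = lapply(report$results, function(r) list(
      within = lapply(r$within, stab_to_list),
      between = stab_to_list(r$between),
      quality = lapply(r$quality, qual_to_list),
      mean_quality = r$mean_quality)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) { x[x == "Inf"] <- Inf; as.numeric(x) }
  results <- lapply(obj$results, function(r) {
    q <- lapply(r$quality, function(qq) {
      qq$per_cluster_q <- num(qq$per_cluster_q)
      qual_from_list(qq)
    })
    list(within = lapply(r$within, stab_from_list),
         between = stab_from_list(r$between),
         quality = q, mean_quality = r$mean_quality)
  })
  structure(list(k_range = as.integer(obj$k_range),
                 conditions = obj$conditions, settings = obj$settings,
                 results = results,
                 selected_k = as.integer(obj$selected_k)),
            class = "validation_report")
}
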