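#' Lesion frequency map
#'
#' Overlays a set of lesion masks: the count at each vertex is the number of
#' patients whose lesion covers it.
#'
#' @param masks nonempty list of [lesion_mask()] objects of equal length
#'   (typically pooled to the left hemisphere first, see [pool_to_left()]).
#' @return an object of class `frequency_map` with elements `counts`
#'   (integer per vertex) and `n_patients`.
#' @export
frequency_map <- function(masks) {
  m <- masks_to_matrix(masks)
  structure(list(counts = as.integer(rowSums(m)),
                 n_patients = ncol(m)),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("frequency_map:", length(x$counts), "vertices,", x$n_patients,
      "patients, max count", max(x$counts), "\n")
  invisible(x)
}

#' Lesion likelihood atlas
#'
#' Normalises a frequency map to \[0, 1\] so the location hit by the most
#' lesions has value exactly 1.
#'
#' @param freq a [frequency_map()] with at least one nonzero count.
#' @return numeric per-vertex map in \[0, 1\].
#' @export
likelihood_atlas <- function(freq) {
  mx <- max(freq$counts)
  if (mx == 0) stop("cannot normalise an all-zero frequency map")
  freq$counts / mx
}

#' Frequency maps stratified by a cohort variable
#'
#' One [frequency_map()] per level of `group_field` (e.g., histopathological
#' subtype, or the operated flag), built from that level's patients only.
#' Levels with no patients are dropped with a warning; patients with `NA`
#' in the grouping variable are excluded.
#'
#' @param cohort a [cohort_table()].
#' @param masks list of [lesion_mask()], one per cohort row.
#' @param group_field name of a cohort column.
#' @return named list of `frequency_map` objects.
#' @export
stratified_maps <- function(cohort, masks, group_field) {
  if (!group_field %in% names(cohort))
    stop("unknown cohort field: ", group_field)
  g <- as.character(cohort[[group_field]])
  levels_seen <- unique(g[!is.na(g)])
  out <- list()
  for (lev in levels_seen) {
    idx <- which(!is.na(g) & g == lev)
    if (!length(idx)) {
      warning("level ", lev, " has no patients; omitted")
      next
    }
    out[[lev]] <- frequency_map(masks[idx])
  }
  out
}

#' Percentage of seizure-free patients by lesion location
#'
#' At each vertex covered by at least one lesion from an operated patient
#' with known outcome, the percentage of those patients who were
#' seizure-free. Vertices with no coverage are `NA`.
#'
#' @param cohort a [cohort_table()]; rows with `NA` outcome are dropped.
#' @param masks list of [lesion_mask()], one per cohort row.
#' @return list with `percent` (numeric per vertex, `NA` where undefined)
#'   and `coverage` (integer lesion count per vertex).
#' @export
percent_seizure_free_map <- function(cohort, masks) {
  keep <- which(!is.na(cohort$seizure_free))
  if (!length(keep)) stop("no patient with recorded outcome")
  m <- masks_to_matrix(masks[keep])
  sf <- as.numeric(cohort$seizure_free[keep])
  coverage <- as.integer(rowSums(m))
  free <- as.vector(m %*% sf)
  percent <- ifelse(coverage > 0, 100 * free / coverage, NA_real_)
  list(percent = percent, coverage = coverage)
}
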