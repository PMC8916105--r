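#' Per-patient binary lesion mask
#'
#' One patient's lesion as a per-vertex 0/1 indicator on the template
#' surface, tagged with the hemisphere it was drawn on.
#'
#' @param patient_id scalar identifier.
#' @param indicator numeric/integer vector of 0/1 over template vertices.
#' @param hemisphere `"left"` or `"right"`.
#' @param allow_empty allow an all-zero mask (used to represent "no mask"
#'   patients); default FALSE.
#' @return an object of class `lesion_mask`.
#' @export
lesion_mask <- function(patient_id, indicator,
                        hemisphere = c("left", "right"),
                        allow_empty = FALSE) {
  hemisphere <- match.arg(hemisphere)
  indicator <- as.integer(indicator)
  if (anyNA(indicator) || !all(indicator %in% c(0L, 1L)))
    stop("lesion indicator must be binary 0/1")
  if (!allow_empty && sum(indicator) == 0L)
    stop("lesion mask for patient ", patient_id, " is empty")
  structure(list(patient_id = patient_id, hemisphere = hemisphere,
                 indicator = indicator),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("lesion_mask: patient", x$patient_id, "-", sum(x$indicator), "of",
      length(x$indicator), "vertices,", x$hemisphere, "hemisphere\n")
  invisible(x)
}

# check a mask matches a mesh (internal)
check_mask_mesh <- function(mask, mesh) {
  if (length(mask$indicator) != n_vertices(mesh))
    stop("mask length (", length(mask$indicator),
         ") does not match mesh vertex count (", n_vertices(mesh), ")")
  invisible(TRUE)
}

#' Stack lesion masks into a vertex-by-patient matrix
#' @param masks list of [lesion_mask()] objects of equal length.
#' @return integer V x n matrix, one column per patient, with patient ids as
#'   column names.
#' @export
masks_to_matrix <- function(masks) {
  if (!length(masks)) stop("empty mask list")
  lens <- vapply(masks, function(m) length(m$indicator), integer(1))
  if (length(unique(lens)) != 1L) stop("masks have differing lengths")
  m <- vapply(masks, function(m) m$indicator, integer(lens[1]))
  colnames(m) <- vapply(masks, function(m) as.character(m$patient_id),
                        character(1))
  m
}

#' Morphological closing of a lesion mask on the mesh graph
#'
#' Fills small defects (holes and slivers) in a lesion mask by `iterations`
#' dilations over the 1-ring adjacency graph followed by the same number of
#' erosions. Closing is extensive (the input is always contained in the
#' output), monotone, and idempotent for a fixed iteration count.
#'
#' @param mask a [lesion_mask()].
#' @param mesh the matching [triangle_mesh()].
#' @param iterations number of dilation (then erosion) steps; default 1,
#'   enough to fill single-vertex defects.
#' @return a closed [lesion_mask()].
#' @export
close_mask <- function(mask, mesh, iterations = 1L) {
  stopifnot(iterations >= 1L)
  check_mask_mesh(mask, mesh)
  adj <- mesh_adjacency(mesh)
  x <- mask$indicator
  dilate <- function(x) {
    as.integer(x | (as.vector(adj %*% x) > 0))
  }
  erode <- function(x) {
    # a vertex survives erosion iff itself and all neighbours are set
    deg <- as.vector(adj %*% rep(1, length(x)))
    as.integer(x & (as.vector(adj %*% x) == deg))
  }
  for (i in seq_len(iterations)) x <- dilate(x)
  for (i in seq_len(iterations)) x <- erode(x)
  lesion_mask(mask$patient_id, as.integer(x | mask$indicator),
              mask$hemisphere, allow_empty = TRUE)
}

#' Lesion size as percentage of hemisphere vertices
#' @param mask a [lesion_mask()].
#' @return numeric in \[0, 100\].
#' @export
lesion_size_pct <- function(mask) {
  100 * sum(mask$indicator) / length(mask$indicator)
}

#' Lobar categorisation of a lesion
#'
#' The lesion is assigned the lobe containing most of its vertices. Lesions
#' falling mostly in the two smallest lobes (cingulate, insula) are
#' reassigned to the overlapping non-cingulate/insula lobe with the largest
#' overlap; if a lesion touches only cingulate/insula it keeps the small
#' lobe. Exact ties are broken in the fixed order frontal, temporal,
#' parietal, occipital, cingulate, insula.
#'
#' @param mask a nonempty [lesion_mask()].
#' @param parc the matching [parcellation()].
#' @return lobe name (character scalar).
#' @export
assign_lobe <- function(mask, parc) {
  if (sum(mask$indicator) == 0L) stop("cannot assign a lobe to an empty mask")
  order_ref <- c("frontal", "temporal", "parietal", "occipital",
                 "cingulate", "insula")
  lv <- lobe_per_vertex(parc)[mask$indicator == 1L]
  counts <- table(factor(lv, levels = order_ref))
  counts <- counts[counts > 0]
  # ties break by position in order_ref because table() keeps level order
  top <- names(counts)[which.max(counts)]
  if (top %in% c("cingulate", "insula")) {
    major <- counts[!names(counts) %in% c("cingulate", "insula")]
    if (length(major)) top <- names(major)[which.max(major)]
  }
  top
}

#' Fraction of a lesion inside eloquent cortex
#'
#' @param mask a nonempty [lesion_mask()].
#' @param eloquent binary vertex map from [eloquent_mask()].
#' @return fraction in \[0, 1\] of lesional vertices that are eloquent.
#' @export
eloquent_overlap <- function(mask, eloquent) {
  if (length(eloquent) != length(mask$indicator))
    stop("eloquent map length does not match mask")
  n_les <- sum(mask$indicator)
  if (n_les == 0L) stop("cannot compute overlap for an empty mask")
  sum(mask$indicator == 1L & eloquent == 1L) / n_les
}

#' Pool lesion masks onto the left hemisphere
#'
#' On a bilaterally symmetric template the left and right hemispheres share
#' vertex indices, so pooling is a re-tag: right-hemisphere masks become
#' left-hemisphere masks with identical indicators.
#'
#' @param masks list of [lesion_mask()] objects.
#' @return list of left-tagged [lesion_mask()] objects.
#' @export
pool_to_left <- function(masks) {
  lapply(masks, function(m) {
    if (m$hemisphere == "left") m
    else lesion_mask(m$patient_id, m$indicator, "left", allow_empty = TRUE)
  })
}
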