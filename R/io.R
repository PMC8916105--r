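#' Read a cohort CSV
#'
#' Reads a cohort table with the documented schema (see [cohort_table()]).
#' Empty cells are treated as unavailable (`NA`); logical columns accept
#' TRUE/FALSE; the result is validated row by row (inconsistent
#' duration/ages, outcomes recorded for non-operated patients, etc. raise
#' an error naming the offending rows).
#'
#' @param path CSV file path.
#' @return a validated [cohort_table()].
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  required <- c("patient_id", "sex", "age_at_scan", "age_at_onset",
                "duration", "ever_mri_negative", "scanner",
                "histopathology", "operated", "seizure_free",
                "follow_up", "lesion_hemisphere")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort CSV lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("ever_mri_negative", "operated", "seizure_free"))
    df[[col]] <- as.logical(df[[col]])
  for (col in c("age_at_scan", "age_at_onset", "duration", "scanner",
                "follow_up"))
    df[[col]] <- as.numeric(df[[col]])
  if ("lesion_size_pct" %in% names(df))
    df$lesion_size_pct <- as.numeric(df$lesion_size_pct)
  if ("eloquent_overlap" %in% names(df))
    df$eloquent_overlap <- as.numeric(df$eloquent_overlap)
  cohort_table(df)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]: `NA` becomes an empty cell; column
#' order follows the schema. Round-trips losslessly through
#' [read_cohort_csv()].
#'
#' @param cohort a [cohort_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write a per-vertex map as plain text
#'
#' Per-vertex scalar maps (atlases, coefficient maps, masks) are stored as
#' one value per line in vertex order - the dependency-free companion to
#' surface overlay formats. Full double precision is preserved; `NA`
#' encodes undefined vertices.
#'
#' @param values numeric per-vertex vector.
#' @param path file path.
#' @return `write_vertex_map` returns `path` invisibly;
#'   `read_vertex_map` returns the numeric vector.
#' @export
write_vertex_map <- function(values, path) {
  out <- ifelse(is.na(values), "NA", sprintf("%.17g", values))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_vertex_map
#' @export
read_vertex_map <- function(path) {
  x <- readLines(path)
  out <- rep(NA_real_, length(x))
  ok <- x != "NA"
  out[ok] <- as.numeric(x[ok])
  out
}

#' Splat a surface atlas into a NIfTI volume
#'
#' Maps a per-vertex atlas back into a 3-D image: each vertex is assigned
#' to the voxel containing its 3-D coordinate (via the inverse affine);
#' voxels hit by several vertices keep the maximum value; untouched voxels
#' are 0. Vertices falling outside the grid are skipped (their count is
#' reported as an attribute).
#'
#' @param atlas numeric per-vertex values (`NA` treated as 0 coverage).
#' @param vertex_coords V x 3 vertex coordinates (mm).
#' @param dim integer length-3 volume dimensions.
#' @param affine 4 x 4 voxel-to-world affine (invertible).
#' @param path optional output path; when given the image is written with
#'   `RNifti::writeNifti`.
#' @return the 3-D array (an `RNifti` image), with attribute
#'   `n_skipped_vertices`.
#' @export
atlas_to_volume <- function(atlas, vertex_coords, dim, affine,
                            path = NULL) {
  stopifnot(length(dim) == 3, all(dim(affine) == c(4, 4)))
  inv <- tryCatch(solve(affine),
                  error = function(e) stop("affine is not invertible"))
  xyz1 <- cbind(vertex_coords, 1)
  vox <- round(xyz1 %*% t(inv))[, 1:3] + 1   # to 1-based voxel indices
  inside <- vox[, 1] >= 1 & vox[, 1] <= dim[1] &
            vox[, 2] >= 1 & vox[, 2] <= dim[2] &
            vox[, 3] >= 1 & vox[, 3] <= dim[3]
  vol <- array(0, dim = dim)
  vals <- ifelse(is.na(atlas), 0, atlas)
  for (i in which(inside)) {
    v <- vox[i, ]
    vol[v[1], v[2], v[3]] <- max(vol[v[1], v[2], v[3]], vals[i])
  }
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  attr(img, "n_skipped_vertices") <- sum(!inside)
  if (!is.null(path)) RNifti::writeNifti(img, path)
  img
}
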