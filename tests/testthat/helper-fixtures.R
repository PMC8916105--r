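# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

fix_mesh <- function() {
  if (is.null(.fix$mesh)) .fix$mesh <- make_sphere_mesh(2)
  .fix$mesh
}

fix_mesh3 <- function() {
  if (is.null(.fix$mesh3)) .fix$mesh3 <- make_sphere_mesh(3)
  .fix$mesh3
}

fix_parc <- function() {
  if (is.null(.fix$parc)) .fix$parc <- make_parcellation(fix_mesh(), 24,
                                                         seed = 2)
  .fix$parc
}

# adjacency list of the 162-vertex fixture mesh
fix_nbrs <- function() {
  if (is.null(.fix$nbrs)) {
    a <- mesh_adjacency(fix_mesh())
    .fix$nbrs <- lapply(seq_len(nrow(a)), function(i) which(a[i, ] > 0))
  }
  .fix$nbrs
}

# Brute-force graph morphology oracle (set-based, independent of the
# sparse-matrix implementation under test).
bf_dilate <- function(set, nbrs) {
  sort(unique(c(set, unlist(nbrs[set]))))
}

bf_erode <- function(set, nbrs) {
  inset <- logical(length(nbrs))
  inset[set] <- TRUE
  keep <- vapply(set, function(v) all(inset[nbrs[[v]]]), logical(1))
  set[keep]
}

bf_close <- function(set, nbrs, k) {
  for (i in seq_len(k)) set <- bf_dilate(set, nbrs)
  for (i in seq_len(k)) set <- bf_erode(set, nbrs)
  set
}

# random connected-ish lesion indicator on the fixture mesh
random_mask_vec <- function(mesh, p = 0.15) {
  as.integer(runif(n_vertices(mesh)) < p)
}

# smooth random scalar field on a mesh (for spin calibration)
smooth_field <- function(mesh, passes = 6) {
  a <- mesh_adjacency(mesh)
  deg <- as.vector(a %*% rep(1, nrow(a)))
  x <- rnorm(nrow(a))
  for (i in seq_len(passes)) x <- 0.8 * as.vector(a %*% x) / deg + 0.2 * x
  x
}

# a null synthetic cohort (no couplings) on the fixture mesh, cached
fix_null_cohort <- function() {
  if (is.null(.fix$null_cohort))
    .fix$null_cohort <- sample_cohort(
      fix_mesh(), fix_parc(),
      simulation_params(n_patients = 80, couplings = NULL, seed = 3))
  .fix$null_cohort
}

# factors genuinely independent of lesion placement in null cohorts
# (lesion size is intrinsically tied to vertex coverage, so it is not part
# of a null calibration spec)
null_factor_spec <- function() {
  factor_spec(factors = c("sex", "age_at_onset", "duration",
                          "ever_mri_negative", "lesion_hemisphere"))
}

# small hand-built cohort data.frame satisfying the schema
toy_cohort <- function(n = 8, seizure_free = NULL) {
  onset <- seq(2, 16, length.out = n)
  dur <- seq(5, 15, length.out = n)
  df <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age_at_scan = onset + dur,
    age_at_onset = onset,
    duration = dur,
    ever_mri_negative = rep(c(TRUE, FALSE), length.out = n),
    scanner = rep(c(1.5, 3), length.out = n),
    histopathology = rep(c("IIA", "IIB"), length.out = n),
    operated = TRUE,
    seizure_free = if (is.null(seizure_free))
      rep(c(TRUE, FALSE), length.out = n) else seizure_free,
    follow_up = rep(2, n),
    lesion_hemisphere = rep(c("left", "right"), length.out = n),
    stringsAsFactors = FALSE)
  cohort_table(df)
}

# disc-shaped mask helper
disc_mask <- function(mesh, center, radius, id = "P1",
                      hemisphere = "left") {
  ind <- integer(n_vertices(mesh))
  ind[geodesic_disc(mesh, center, radius)] <- 1L
  lesion_mask(id, ind, hemisphere)
}
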