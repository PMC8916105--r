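#' Uniformly distributed random 3-D rotation
#'
#' Proper rotation matrix (orthonormal, determinant +1) drawn uniformly
#' from SO(3) via QR decomposition of a Gaussian matrix with sign fixing.
#'
#' @param seed optional integer seed; when supplied the rotation is
#'   reproducible.
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  # make the distribution Haar-uniform: fix the signs by R's diagonal
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# check a matrix is a rotation (internal)
check_rotation <- function(rotation) {
  if (!is.matrix(rotation) || any(dim(rotation) != 3) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be a 3 x 3 orthogonal matrix")
  invisible(TRUE)
}

#' Spin (spherically rotate) a per-vertex map
#'
#' Rotates the registration sphere and resamples the map by nearest
#' neighbour: the rotated value at vertex v is the original value at the
#' vertex closest (greatest dot product on the unit sphere) to the rotated
#' position of v. The identity rotation returns the map unchanged.
#'
#' @param map numeric per-vertex map.
#' @param sphere_coords V x 3 unit-sphere coordinates (e.g.,
#'   `mesh$sphere_coords`).
#' @param rotation 3 x 3 rotation matrix.
#' @return rotated map (numeric, same length).
#' @export
spin_map <- function(map, sphere_coords, rotation) {
  check_rotation(rotation)
  stopifnot(length(map) == nrow(sphere_coords))
  map[spin_index(sphere_coords, rotation)]
}

# nearest-original-vertex index after rotating the sphere (internal)
spin_index <- function(sphere_coords, rotation) {
  rotated <- sphere_coords %*% t(rotation)
  max.col(rotated %*% t(sphere_coords), ties.method = "first")
}

#' Precomputed spin resampling indices
#'
#' Draws `n_rotations` uniform rotations and returns the nearest-vertex
#' resampling index for each, as a V x n_rotations matrix. Rotating a map
#' is then `map[idx[, k]]`. Precomputing the indices lets many map pairs
#' share one null rotation set.
#'
#' @param sphere_coords V x 3 unit-sphere coordinates.
#' @param n_rotations number of rotations.
#' @param seed integer RNG seed.
#' @return integer V x n_rotations index matrix.
#' @export
spin_indices <- function(sphere_coords, n_rotations, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_rotations),
         function(k) spin_index(sphere_coords, random_rotation()),
         integer(nrow(sphere_coords)))
}

#' Spin test for the correlation of two cortical maps
#'
#' Tests the Spearman correlation between two per-vertex maps against a
#' null that preserves spatial autocorrelation: one map is resampled under
#' random spherical rotations and the correlation recomputed per rotation.
#' The two-sided p-value is `(1 + #{|null r| >= |observed r|}) /
#' (1 + n_rotations)`.
#'
#' @param map_a,map_b numeric per-vertex maps (full template length).
#' @param mesh a [triangle_mesh()] supplying `sphere_coords`.
#' @param n_rotations number of rotations (default 1000).
#' @param seed integer RNG seed.
#' @param indices optional precomputed [spin_indices()] matrix (overrides
#'   `n_rotations`/`seed`).
#' @return object of class `spin_test`: `r_rank`, `null_r`, `p_spin`,
#'   `n_rotations`, `seed`.
#' @export
spin_correlation_test <- function(map_a, map_b, mesh, n_rotations = 1000,
                                  seed = 1L, indices = NULL) {
  stopifnot(length(map_a) == n_vertices(mesh),
            length(map_b) == n_vertices(mesh))
  if (sd(map_a) < 1e-12 || sd(map_b) < 1e-12)
    stop("correlation undefined for a constant map")
  if (is.null(indices))
    indices <- spin_indices(mesh$sphere_coords, n_rotations, seed)
  n_rotations <- ncol(indices)
  r_rank <- cor(map_a, map_b, method = "spearman")
  rb <- rank(map_b)   # rank once; rotation permutes map_a only
  null_r <- vapply(seq_len(n_rotations), function(k) {
    cor(rank(map_a[indices[, k]]), rb)
  }, numeric(1))
  p_spin <- (1 + sum(abs(null_r) >= abs(r_rank))) / (1 + n_rotations)
  structure(list(r_rank = r_rank, null_r = null_r, p_spin = p_spin,
                 n_rotations = n_rotations, seed = seed),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("spin_test: r_rank = %.3f, p_spin = %.4g (%d rotations)\n",
              x$r_rank, x$p_spin, x$n_rotations))
  invisible(x)
}
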