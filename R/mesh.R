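#' Template triangle mesh
#'
#' Container for one hemisphere of a template cortical surface: 3-D vertex
#' positions, triangular faces, and the matching unit-sphere coordinates used
#' for registration and spin rotations. Vertices are indexed 1..V inside R;
#' files written by [write_vertex_map()] and friends preserve vertex order so
#' 0-based tools line up row by row.
#'
#' @param vertex_coords numeric V x 3 matrix of vertex positions (mm).
#' @param faces integer F x 3 matrix of vertex indices (1-based) forming
#'   triangles.
#' @param sphere_coords numeric V x 3 matrix of unit vectors on the
#'   registration sphere; defaults to `vertex_coords` normalised to unit
#'   length.
#' @param hemisphere `"left"` or `"right"`.
#'
#' @return An object of class `triangle_mesh` with elements `vertex_coords`,
#'   `faces`, `sphere_coords`, `hemisphere`.
#' @seealso [make_sphere_mesh()] for the synthetic icosphere template.
#' @export
triangle_mesh <- function(vertex_coords, faces, sphere_coords = NULL,
                          hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertex_coords <- as.matrix(vertex_coords)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertex_coords) == 3, ncol(faces) == 3)
  nv <- nrow(vertex_coords)
  if (any(faces < 1L) || any(faces > nv))
    stop("face indices must lie in 1..", nv)
  if (is.null(sphere_coords)) {
    nrm <- sqrt(rowSums(vertex_coords^2))
    if (any(nrm == 0)) stop("cannot derive sphere_coords: zero-length vertex")
    sphere_coords <- vertex_coords / nrm
  }
  sphere_coords <- as.matrix(sphere_coords)
  stopifnot(nrow(sphere_coords) == nv, ncol(sphere_coords) == 3)
  bad <- abs(sqrt(rowSums(sphere_coords^2)) - 1) > 1e-6
  if (any(bad))
    stop(sum(bad), " sphere_coords rows are not unit vectors")
  mesh <- structure(
    list(vertex_coords = vertex_coords, faces = faces,
         sphere_coords = sphere_coords, hemisphere = hemisphere),
    class = "triangle_mesh")
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L)
    stop("mesh 1-ring adjacency graph is not connected")
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", n_vertices(x), "vertices,", nrow(x$faces),
      "faces,", x$hemisphere, "hemisphere\n")
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a [triangle_mesh()].
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertex_coords)

#' Sparse 1-ring adjacency matrix
#'
#' Symmetric V x V sparse 0/1 matrix with `A[i, j] = 1` when vertices i and j
#' share a mesh edge. Cached on the mesh object by the internal callers.
#'
#' @param mesh a [triangle_mesh()].
#' @return a `Matrix::sparseMatrix` (pattern symmetric).
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  nv <- n_vertices(mesh)
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(nv, nv))
  (a > 0) * 1
}

# igraph view of the 1-ring adjacency (internal)
mesh_graph <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  igraph::graph_from_edgelist(edges, directed = FALSE) |>
    igraph::simplify()
}

#' Graph-geodesic ring distance from seed vertices
#'
#' Breadth-first distance (in 1-ring hops) from a set of seed vertices to
#' every vertex of the mesh. This ring metric stands in for geodesic
#' distance throughout the package (disc growth, parcellation).
#'
#' @param mesh a [triangle_mesh()].
#' @param seeds integer vector of seed vertex indices.
#' @return if one seed, an integer vector of hop counts; if several, a
#'   matrix with one row per seed.
#' @export
mesh_ring_distance <- function(mesh, seeds) {
  d <- igraph::distances(mesh_graph(mesh), v = seeds)
  if (length(seeds) == 1L) as.integer(d[1, ]) else d
}

#' Geodesic disc of vertices
#'
#' All vertices within `radius` rings of `center` (inclusive).
#'
#' @param mesh a [triangle_mesh()].
#' @param center seed vertex index.
#' @param radius nonnegative integer ring radius.
#' @return integer vector of vertex indices.
#' @export
geodesic_disc <- function(mesh, center, radius) {
  stopifnot(radius >= 0)
  which(mesh_ring_distance(mesh, center) <= radius)
}
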