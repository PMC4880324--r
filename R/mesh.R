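#' Triangle surface mesh
#'
#' Constructs the surface container used throughout the package: vertices in
#' world millimetres and triangular faces as 1-based vertex-index triples.
#'
#' @param vertices numeric matrix, one row per vertex, three columns (x, y, z)
#'   in mm.
#' @param faces integer matrix, one row per triangle, three columns of 1-based
#'   vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- icosphere(1)
#' m
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
      stop("degenerate face references a vertex twice")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- mesh_bounds(x)
  cat(sprintf("  bounds [mm]: x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb$min[1], bb$max[1], bb$min[2], bb$max[2], bb$min[3], bb$max[3]))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return list with numeric `min` and `max` corners (mm).
#' @export
mesh_bounds <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) stop("empty mesh has no bounds")
  list(min = apply(mesh$vertices, 2, min),
       max = apply(mesh$vertices, 2, max))
}

# Directed edge census. A closed orientable surface has every undirected edge
# shared by exactly two faces with opposite orientation.
mesh_edge_census <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  key_und <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key_und)
  list(
    n_boundary = sum(tab == 1L),
    n_nonmanifold = sum(tab > 2L),
    oriented = !anyDuplicated(key_dir)
  )
}

#' Test whether a mesh is a closed (watertight) surface
#'
#' A mesh is watertight when every edge is shared by exactly two consistently
#' oriented triangles; inside/outside queries (rasterization) require this.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical scalar; attribute `"boundary_edges"` carries the count of
#'   open edges.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(structure(FALSE, boundary_edges = 0L))
  cen <- mesh_edge_census(mesh)
  structure(cen$n_boundary == 0L && cen$n_nonmanifold == 0L && cen$oriented,
            boundary_edges = cen$n_boundary)
}

stop_if_not_watertight <- function(mesh, what = "operation") {
  wt <- is_watertight(mesh)
  if (!wt)
    stop(sprintf("%s requires a watertight mesh (%d boundary edge(s) found)",
                 what, attr(wt, "boundary_edges")))
  invisible(TRUE)
}

#' Subdivided icosahedral sphere
#'
#' Unit sphere approximated by recursive 4-way subdivision of an icosahedron,
#' the standard spherical phantom discretization (level 4 gives 2562 vertices,
#' 5120 faces). Outward-oriented and watertight by construction.
#'
#' @param subdivisions non-negative integer subdivision level.
#' @return a [triangle_mesh()] with vertices on the unit sphere.
#' @export
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint cache keyed on the undirected edge
    ekey <- function(a, b) pmin(a, b) * (nv + 1L) + pmax(a, b)
    e12 <- ekey(f[, 1], f[, 2]); e23 <- ekey(f[, 2], f[, 3])
    e31 <- ekey(f[, 3], f[, 1])
    all_keys <- c(e12, e23, e31)
    uk <- unique(all_keys)
    midx <- match(all_keys, uk) + nv
    a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
    first <- !duplicated(match(all_keys, uk))
    mids <- (v[a[first], , drop = FALSE] + v[b[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    # order midpoints by their key index so row nv+r matches uk[r]
    ord <- order(match(all_keys[first], uk))
    v <- rbind(v, mids[ord, , drop = FALSE])
    nf <- nrow(f)
    m12 <- midx[seq_len(nf)]
    m23 <- midx[nf + seq_len(nf)]
    m31 <- midx[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  triangle_mesh(v, f)
}

#' Ellipsoid surface mesh
#'
#' Icosphere scaled anisotropically to the given semi-axes and translated to
#' `center`; the ground-truth organ phantom used by the fixture generator.
#'
#' @param center numeric length-3 world center (mm).
#' @param radii numeric length-3 strictly positive semi-axes (mm).
#' @param subdivisions icosphere subdivision level.
#' @return a [triangle_mesh()].
#' @export
ellipsoid_mesh <- function(center, radii, subdivisions = 4L) {
  if (any(radii <= 0)) stop("radii must be strictly positive")
  m <- icosphere(subdivisions)
  v <- sweep(sweep(m$vertices, 2, radii, `*`), 2, center, `+`)
  triangle_mesh(v, m$faces)
}

#' Translate a mesh
#' @param mesh a [triangle_mesh()].
#' @param offset numeric length-3 translation (mm).
#' @return translated [triangle_mesh()].
#' @export
translate_mesh <- function(mesh, offset) {
  triangle_mesh(sweep(mesh$vertices, 2, offset, `+`), mesh$faces)
}
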