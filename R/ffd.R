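#' Trivariate Bernstein control lattice
#'
#' The free-form deformation lattice: a parallelepiped with origin `X0` and
#' edge vectors S, T, U, carrying an `(l+1) x (m+1) x (n+1)` array of control
#' points. In the undeformed state control point `(i,j,k)` sits at
#' `X0 + (i/l) S + (j/m) T + (k/n) U` and all displacements are zero; shape
#' edits act only on the displacements, never on the lattice geometry.
#'
#' Control points are stored as a `C x 3` matrix in index order `i` fastest,
#' then `j`, then `k` (see [grid_index()]).
#'
#' @param origin numeric length-3 world origin X0 (mm).
#' @param axes 3x3 numeric matrix whose columns are the edge vectors S, T, U
#'   (mm); must be linearly independent.
#' @param degrees integer length-3 polynomial degrees (l, m, n), each >= 1.
#' @return An object of class `control_grid`.
#' @export
control_grid <- function(origin, axes, degrees) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  degrees <- as.integer(degrees)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be a finite length-3 vector")
  if (!all(dim(axes) == c(3L, 3L)) || !all(is.finite(axes)))
    stop("axes must be a finite 3x3 matrix (columns S, T, U)")
  if (length(degrees) != 3L || any(degrees < 1L))
    stop("degrees must be three integers >= 1")
  if (abs(det(axes)) < 1e-12)
    stop("singular lattice frame: S, T, U must be linearly independent")
  cp <- lattice_positions(origin, axes, degrees)
  structure(list(origin = origin, axes = axes, degrees = degrees,
                 control_points = cp,
                 displacements = matrix(0, nrow(cp), 3L)),
            class = "control_grid")
}

# Regular lattice positions in canonical index order (i fastest).
lattice_positions <- function(origin, axes, degrees) {
  l <- degrees[1]; m <- degrees[2]; n <- degrees[3]
  g <- expand.grid(i = 0:l, j = 0:m, k = 0:n)
  frac <- cbind(g$i / l, g$j / m, g$k / n)
  sweep(frac %*% t(axes), 2, origin, `+`)
}

#' Linear index of control point (i, j, k)
#'
#' @param degrees integer length-3 degrees (l, m, n).
#' @param i,j,k 0-based lattice indices.
#' @return 1-based row index into the control-point matrix.
#' @export
grid_index <- function(degrees, i, j, k) {
  1L + i + (degrees[1] + 1L) * (j + (degrees[2] + 1L) * k)
}

#' Number of control points of a grid
#' @param grid a [control_grid()].
#' @return integer `(l+1)(m+1)(n+1)`.
#' @export
n_control_points <- function(grid) prod(grid$degrees + 1L)

#' @export
print.control_grid <- function(x, ...) {
  cat(sprintf("control_grid: degrees (%d,%d,%d), %d control points\n",
              x$degrees[1], x$degrees[2], x$degrees[3], n_control_points(x)))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) mm; edge lengths %.3f / %.3f / %.3f mm\n",
              x$origin[1], x$origin[2], x$origin[3],
              sqrt(sum(x$axes[, 1]^2)), sqrt(sum(x$axes[, 2]^2)),
              sqrt(sum(x$axes[, 3]^2))))
  if (any(x$displacements != 0))
    cat(sprintf("  max |displacement| %.4f mm\n",
                max(sqrt(rowSums(x$displacements^2)))))
  invisible(x)
}

# Univariate Bernstein basis values: rows = evaluation points, cols = 0..d.
bernstein_basis_1d <- function(d, x) {
  i <- 0:d
  outer(x, i, function(xx, ii) choose(d, ii) * (1 - xx)^(d - ii) * xx^ii)
}

#' Trivariate Bernstein weights
#'
#' Tensor-product Bernstein weights of a lattice point: the contribution of
#' every control point `(i,j,k)` to the deformed position of a point with
#' local coordinates `(s,t,u)`. Weights sum to one for any coordinates
#' (binomial theorem), which is what makes the deformation interpolate
#' rigid translations exactly.
#'
#' @param degrees integer length-3 degrees (l, m, n).
#' @param coords either a numeric length-3 vector `(s,t,u)` or an `N x 3`
#'   matrix of local coordinates.
#' @return For a single triple, a 3-D array of dimension
#'   `(l+1, m+1, n+1)`; for a matrix, an `N x C` weight matrix in
#'   [grid_index()] column order.
#' @examples
#' w <- bernstein_weights(c(1, 1, 1), c(0.5, 0.5, 0.5))
#' all(w == 0.125)
#' @export
bernstein_weights <- function(degrees, coords) {
  degrees <- as.integer(degrees)
  if (length(degrees) != 3L || any(degrees < 0L))
    stop("degrees must be three non-negative integers")
  single <- is.null(dim(coords))
  cm <- if (single) matrix(as.numeric(coords), 1L, 3L) else as.matrix(coords)
  if (ncol(cm) != 3L) stop("coords must have 3 columns (s, t, u)")
  if (!all(is.finite(cm))) stop("non-finite local coordinates")
  W <- bernstein_weight_matrix(degrees, cm)
  if (single) array(W[1L, ], dim = degrees + 1L) else W
}

# N x C tensor-product weight matrix, i fastest (grid_index order).
bernstein_weight_matrix <- function(degrees, coords) {
  Bs <- bernstein_basis_1d(degrees[1], coords[, 1])
  Bt <- bernstein_basis_1d(degrees[2], coords[, 2])
  Bu <- bernstein_basis_1d(degrees[3], coords[, 3])
  g <- expand.grid(i = seq_len(degrees[1] + 1L),
                   j = seq_len(degrees[2] + 1L),
                   k = seq_len(degrees[3] + 1L))
  Bs[, g$i, drop = FALSE] * Bt[, g$j, drop = FALSE] * Bu[, g$k, drop = FALSE]
}

#' Fit a global control grid around a mesh
#'
#' Axis-aligned lattice covering the mesh bounding box, expanded by a padding
#' fraction of each extent on every side so boundary vertices sit strictly
#' inside the lattice and outward drags have room to act.
#'
#' @param mesh a [triangle_mesh()].
#' @param degrees integer length-3 degrees; the default `(5,5,5)` yields the
#'   216-control-point lattice used as the tool's standard configuration.
#' @param padding non-negative fraction of each bounding-box extent added on
#'   both sides (default 0.05).
#' @return a [control_grid()] in which every mesh vertex embeds with
#'   `(s,t,u)` in `[0,1]^3`.
#' @export
fit_global_grid <- function(mesh, degrees = c(5L, 5L, 5L), padding = 0.05) {
  if (padding < 0) stop("padding must be >= 0")
  bb <- mesh_bounds(mesh)
  ext <- bb$max - bb$min
  ax <- c("x", "y", "z")[ext <= 0]
  if (length(ax) > 0)
    stop(sprintf("degenerate mesh: zero extent along axis %s",
                 paste(ax, collapse = ", ")))
  pad <- padding * ext
  control_grid(origin = bb$min - pad, axes = diag(ext + 2 * pad),
               degrees = degrees)
}

#' Fit a local control grid at a region of interest
#'
#' Axis-aligned lattice of the same degrees (hence the same number of control
#' points) centered on a user-chosen region; shrinking the lattice onto the
#' error region concentrates the full deformation resolution there at no
#' extra computational cost, and vertices outside the lattice are left
#' untouched by [deform_mesh()].
#'
#' @param center numeric length-3 world center (mm).
#' @param size numeric length-3 strictly positive edge lengths (mm).
#' @param degrees integer length-3 degrees (default `(5,5,5)`).
#' @return a [control_grid()].
#' @export
fit_local_grid <- function(center, size, degrees = c(5L, 5L, 5L)) {
  center <- as.numeric(center); size <- as.numeric(size)
  if (length(size) != 3L || any(size <= 0))
    stop("local grid size must be strictly positive on all three axes")
  control_grid(origin = center - size / 2, axes = diag(size),
               degrees = degrees)
}

# slack for the inside-[0,1] test, absorbing float jitter at lattice faces
EMBED_TOL <- 1e-9

#' Embed mesh vertices in a lattice
#'
#' Computes the local coordinates `(s,t,u)` of every vertex by inverting the
#' affine frame `x = X0 + s S + t T + u U` (exact linear solve; valid for any
#' non-degenerate, possibly sheared parallelepiped). Vertices with any
#' coordinate outside `[0,1]` are flagged non-embedded; they are ignored by
#' the solver and left unchanged by [deform_mesh()], which is what confines a
#' local grid's influence to its region.
#'
#' @param mesh a [triangle_mesh()].
#' @param grid a [control_grid()].
#' @return An object of class `local_coords`: list with `coords` (`V x 3`),
#'   logical `embedded` (length V), and the grid signature used for
#'   mismatch checks.
#' @export
embed_mesh <- function(mesh, grid) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(grid, "control_grid"))
  d <- sweep(mesh$vertices, 2, grid$origin, `-`)
  stu <- t(solve(grid$axes, t(d)))
  emb <- stu[, 1] >= -EMBED_TOL & stu[, 1] <= 1 + EMBED_TOL &
    stu[, 2] >= -EMBED_TOL & stu[, 2] <= 1 + EMBED_TOL &
    stu[, 3] >= -EMBED_TOL & stu[, 3] <= 1 + EMBED_TOL
  structure(list(coords = stu, embedded = emb,
                 signature = grid_signature(grid), n_vertices = nrow(stu)),
            class = "local_coords")
}

grid_signature <- function(grid) {
  c(grid$origin, as.numeric(grid$axes), as.numeric(grid$degrees))
}

check_coords_match <- function(coords, mesh, grid) {
  if (!inherits(coords, "local_coords"))
    stop("coords must come from embed_mesh()")
  if (coords$n_vertices != nrow(mesh$vertices))
    stop("coords/mesh mismatch: vertex counts differ")
  if (!isTRUE(all.equal(coords$signature, grid_signature(grid),
                        tolerance = 1e-12)))
    stop("coords/grid mismatch: coordinates were computed against a different grid")
  invisible(TRUE)
}

#' Apply the free-form deformation to a mesh
#'
#' Each embedded vertex moves to the Bernstein-weighted combination of the
#' displaced control points,
#' `x_ffd = sum_ijk w_ijk(s,t,u) (P_ijk + dP_ijk)`.
#' Since the undisplaced lattice lies on the affine frame and Bernstein
#' polynomials reproduce affine functions, `sum w P` is the vertex position
#' itself, so the update is evaluated in the equivalent displacement form
#' `x_ffd = x + W dP`, which leaves the mesh bit-identical when all
#' displacements are zero. Vertices outside the lattice (local mode) are
#' returned bitwise unchanged; faces are preserved.
#'
#' @param mesh a [triangle_mesh()].
#' @param coords local coordinates from [embed_mesh()] against `grid`.
#' @param grid a [control_grid()] whose `displacements` drive the deformation.
#' @return the deformed [triangle_mesh()] (the input is not modified).
#' @export
deform_mesh <- function(mesh, coords, grid) {
  check_coords_match(coords, mesh, grid)
  v <- mesh$vertices
  emb <- coords$embedded
  if (any(emb) && any(grid$displacements != 0)) {
    W <- bernstein_weight_matrix(grid$degrees,
                                 coords$coords[emb, , drop = FALSE])
    v[emb, ] <- v[emb, , drop = FALSE] + W %*% grid$displacements
  }
  triangle_mesh(v, mesh$faces)
}

#' Serialize a control grid to JSON
#'
#' Plain JSON document (origin, axes, degrees, control points, displacements)
#' so a correction session's lattice state is reproducible.
#'
#' @param grid a [control_grid()].
#' @param path output file path.
#' @export
write_grid_json <- function(grid, path) {
  jsonlite::write_json(
    list(origin = grid$origin,
         axes = as.data.frame(grid$axes),
         degrees = grid$degrees,
         control_points = as.data.frame(grid$control_points),
         displacements = as.data.frame(grid$displacements)),
    path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read a control grid from JSON
#' @param path file written by [write_grid_json()].
#' @return a [control_grid()] with displacements restored.
#' @export
read_grid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- control_grid(unlist(x$origin), as.matrix(x$axes),
                    unlist(x$degrees))
  g$control_points <- unname(as.matrix(x$control_points))
  g$displacements <- unname(as.matrix(x$displacements))
  g
}
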