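#' Deformation constraint
#'
#' One desired vertex displacement: "move this vertex by this vector". The
#' inverse-FFD solver finds lattice displacements realizing all constraints.
#'
#' @param vertex_id 1-based index into the mesh vertices.
#' @param displacement numeric length-3 target displacement (mm).
#' @return a `ffd_constraint` object.
#' @export
ffd_constraint <- function(vertex_id, displacement) {
  vertex_id <- as.integer(vertex_id)
  displacement <- as.numeric(displacement)
  if (length(vertex_id) != 1L || is.na(vertex_id) || vertex_id < 1L)
    stop("vertex_id must be a single positive index")
  if (length(displacement) != 3L || !all(is.finite(displacement)))
    stop("displacement must be a finite length-3 vector (mm)")
  structure(list(vertex_id = vertex_id, displacement = displacement),
            class = "ffd_constraint")
}

#' Inverse FFD: solve control-point displacements from vertex constraints
#'
#' The direct-manipulation step. Each constrained vertex contributes one row
#' of Bernstein weights B over all control points; the lattice displacements
#' are the minimum-norm least-squares solution of `B dP = dX`
#' (Moore-Penrose pseudoinverse), solved independently per spatial component
#' since the weight matrix is shared. With a single constraint this reduces
#' to the closed form `dP_ijk = w_ijk dX / sum(w^2)` and the constraint is
#' met exactly; rank-deficient multi-constraint systems are resolved in the
#' least-squares sense and the residual is reported via a warning.
#'
#' @param grid a [control_grid()] (its current displacements are replaced).
#' @param coords local coordinates of the mesh from [embed_mesh()].
#' @param constraints a list of [ffd_constraint()] objects (at least one).
#' @return the grid with `displacements` filled.
#' @export
solve_displacements <- function(grid, coords, constraints) {
  if (inherits(constraints, "ffd_constraint")) constraints <- list(constraints)
  if (length(constraints) == 0L) stop("at least one constraint is required")
  ids <- vapply(constraints, function(cn) cn$vertex_id, integer(1))
  if (any(ids > coords$n_vertices)) stop("constraint vertex_id out of range")
  if (!all(coords$embedded[ids]))
    stop("constrained vertex lies outside the control lattice (not embedded)")
  dX <- t(vapply(constraints, function(cn) cn$displacement, numeric(3)))
  B <- bernstein_weight_matrix(grid$degrees,
                               coords$coords[ids, , drop = FALSE])
  if (any(rowSums(B^2) <= 0))
    stop("constraint has an all-zero weight row (vertex outside grid)")
  if (nrow(B) == 1L) {
    dP <- (t(B) %*% dX) / sum(B^2)
  } else {
    dP <- MASS::ginv(B) %*% dX
    resid <- max(abs(B %*% dP - dX))
    if (resid > 1e-8)
      warning(sprintf(
        "conflicting constraints: solved in the least-squares sense (max residual %.3g mm)",
        resid))
  }
  grid$displacements <- dP
  grid
}

#' Apply one contour drag to a mesh
#'
#' The per-interaction pipeline: embed the current mesh in the given
#' (zero-displacement) lattice, solve the inverse FFD for the single dragged
#' vertex, and apply the forward deformation. The dragged vertex lands on its
#' requested target (exactly, up to float round-off) while the surrounding
#' surface follows smoothly with Bernstein-weight falloff; with a local grid,
#' vertices outside the lattice do not move at all.
#'
#' @param mesh a [triangle_mesh()].
#' @param grid a [control_grid()]; typically freshly fitted to `mesh` by
#'   [fit_global_grid()] or [fit_local_grid()].
#' @param vertex_id index of the dragged vertex.
#' @param displacement numeric length-3 drag vector (mm).
#' @return the deformed [triangle_mesh()] (a new object; input untouched).
#' @export
apply_drag <- function(mesh, grid, vertex_id, displacement) {
  coords <- embed_mesh(mesh, grid)
  grid <- solve_displacements(grid, coords,
                              list(ffd_constraint(vertex_id, displacement)))
  deform_mesh(mesh, coords, grid)
}
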