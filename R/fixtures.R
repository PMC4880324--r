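#' Correction configuration
#'
#' The tunable parameters of the correction engine: lattice degrees (the
#' default `(5,5,5)` is the standard 216-control-point configuration),
#' global-grid padding as a fraction of each bounding-box extent, and the
#' deterministic local-grid sizing rule (grid edge = `local_size_factor`
#' times the local error magnitude, floored at `local_floor_voxels` voxels).
#'
#' @param degrees integer length-3 lattice degrees.
#' @param padding global-grid padding fraction.
#' @param local_size_factor local grid edge per mm of local error.
#' @param local_floor_voxels minimum local grid edge in voxels.
#' @return a `correction_config` list.
#' @export
correction_config <- function(degrees = c(5L, 5L, 5L), padding = 0.05,
                              local_size_factor = 3, local_floor_voxels = 4) {
  structure(list(degrees = as.integer(degrees), padding = padding,
                 local_size_factor = local_size_factor,
                 local_floor_voxels = local_floor_voxels),
            class = "correction_config")
}

#' Synthetic fixture specification
#'
#' Describes a reproducible test case: image geometry, an ellipsoidal
#' ground-truth organ, and the systematic perturbation that turns the ground
#' truth into an imperfect "initial segmentation" standing in for an
#' automatic segmenter's output.
#'
#' @param geometry an [image_geometry()].
#' @param center numeric length-3 ellipsoid center (mm).
#' @param radii numeric length-3 semi-axes (mm).
#' @param perturbation list with `kind` ("global_scale", "smooth_bump" or
#'   "random_ffd"), `magnitude` (scale factor for global_scale; mm for
#'   smooth_bump; mm s.d. for random_ffd), optional `seed` (default 1) and,
#'   for smooth_bump, optional angular `width` in radians (default 0.7).
#' @param mesh_resolution icosphere subdivision level (default 4, i.e. 2562
#'   vertices).
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(geometry, center, radii,
                         perturbation = list(kind = "global_scale",
                                             magnitude = 1.10, seed = 1L),
                         mesh_resolution = 4L) {
  stopifnot(inherits(geometry, "image_geometry"))
  if (any(radii <= 0)) stop("radii must be strictly positive")
  perturbation$kind <- match.arg(perturbation$kind,
                                 c("global_scale", "smooth_bump", "random_ffd"))
  if (is.null(perturbation$seed)) perturbation$seed <- 1L
  if (is.null(perturbation$magnitude)) stop("perturbation needs a magnitude")
  structure(list(geometry = geometry, center = as.numeric(center),
                 radii = as.numeric(radii), perturbation = perturbation,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "fixture_spec")
}

#' Default study fixture: 10%-oversized sphere
#'
#' The canonical end-to-end case: a spherical organ of radius 16 mm in an
#' isotropic 0.8 mm, 64^3 volume, with an initial segmentation inflated by a
#' global scale factor of 1.10. The analytic Dice of the nested balls,
#' `2 r^3 / (r^3 + (1.1 r)^3) = 0.8586`, matches the quality regime of
#' typical automatic model-based segmentations before correction.
#'
#' @param scale global scale error (default 1.10).
#' @param seed perturbation seed.
#' @return a `fixture_spec`.
#' @export
default_sphere_fixture <- function(scale = 1.10, seed = 1L) {
  geom <- image_geometry(shape = c(64L, 64L, 64L),
                         spacing = c(0.8, 0.8, 0.8),
                         origin = c(0, 0, 0))
  center <- geom$origin + (geom$shape - 1) / 2 * geom$spacing
  fixture_spec(geom, center = center, radii = c(16, 16, 16),
               perturbation = list(kind = "global_scale", magnitude = scale,
                                   seed = seed))
}

#' Build a synthetic correction fixture
#'
#' Produces the ground-truth mask (analytic inside-ellipsoid test at voxel
#' centers), the ground-truth surface mesh (subdivided icosphere scaled to
#' the ellipsoid) and the perturbed initial segmentation mesh. Deterministic:
#' the same spec (including its seed) always yields bitwise-identical
#' fixtures; the caller's RNG state is left untouched.
#'
#' @param spec a [fixture_spec()].
#' @return list with `gt_mask` (`seg_mask`), `gt_mesh`, `initial_mesh`
#'   ([triangle_mesh()]) and the `spec`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  gt_mesh <- ellipsoid_mesh(spec$center, spec$radii, spec$mesh_resolution)
  gt_mask <- ellipsoid_mask(spec$geometry, spec$center, spec$radii)
  initial <- perturb_mesh(gt_mesh, spec)
  list(gt_mask = gt_mask, gt_mesh = gt_mesh, initial_mesh = initial,
       spec = spec)
}

perturb_mesh <- function(gt_mesh, spec) {
  p <- spec$perturbation
  v <- gt_mesh$vertices
  center <- spec$center
  rmin <- min(spec$radii)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)
  if (p$kind == "global_scale") {
    if (p$magnitude <= 0) stop("global_scale magnitude must be positive")
    v2 <- sweep(sweep(v, 2, center, `-`) * p$magnitude, 2, center, `+`)
  } else if (p$kind == "smooth_bump") {
    # cosine-windowed radial bump: self-intersection-free only while the
    # perturbed surface stays star-shaped about the center
    if (abs(p$magnitude) >= rmin / 2)
      stop("smooth_bump magnitude would self-intersect the surface (|magnitude| must be < min radius / 2)")
    width <- if (is.null(p$width)) 0.7 else p$width
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    d <- sweep(v, 2, center, `-`)
    r <- sqrt(rowSums(d^2))
    ang <- acos(pmin(pmax(as.numeric(d %*% dirv) / r, -1), 1))
    w <- ifelse(ang < width, 0.5 * (1 + cos(pi * ang / width)), 0)
    v2 <- v + (d / r) * (p$magnitude * w)
  } else {  # random_ffd
    if (p$magnitude >= rmin / 4)
      stop("random_ffd magnitude too large: risk of self-intersection (must be < min radius / 4)")
    grid <- fit_global_grid(gt_mesh, degrees = c(2L, 2L, 2L), padding = 0.05)
    grid$displacements <- matrix(stats::rnorm(3 * n_control_points(grid),
                                              sd = p$magnitude),
                                 n_control_points(grid), 3L)
    coords <- embed_mesh(gt_mesh, grid)
    return(deform_mesh(gt_mesh, coords, grid))
  }
  triangle_mesh(v2, gt_mesh$faces)
}

#' Write a fixture to a case directory
#'
#' Emits the ground-truth mask (NIfTI), ground-truth and initial meshes
#' (PLY) and the fixture spec (JSON) into `dir`.
#'
#' @param fixture result of [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask_nifti(fixture$gt_mask, file.path(dir, "gt.nii.gz"))
  write_mesh(fixture$gt_mesh, file.path(dir, "gt.ply"))
  write_mesh(fixture$initial_mesh, file.path(dir, "initial.ply"))
  s <- fixture$spec
  jsonlite::write_json(
    list(geometry = list(shape = s$geometry$shape,
                         spacing = s$geometry$spacing,
                         origin = s$geometry$origin),
         center = s$center, radii = s$radii,
         perturbation = s$perturbation,
         mesh_resolution = s$mesh_resolution),
    file.path(dir, "spec.json"), digits = I(17), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture spec from JSON
#' @param path `spec.json` written by [write_fixture()].
#' @return a [fixture_spec()].
#' @export
read_fixture_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_spec(image_geometry(x$geometry$shape, x$geometry$spacing,
                              x$geometry$origin),
               center = x$center, radii = x$radii,
               perturbation = as.list(x$perturbation),
               mesh_resolution = x$mesh_resolution)
}
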