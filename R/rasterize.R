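#' Binary segmentation mask
#'
#' A 3-D logical array tied to an [image_geometry()]; all mask arithmetic
#' (Dice, IO) checks geometry identity explicitly — masks on mismatched
#' grids are never silently resampled.
#'
#' @param data logical or 0/1 3-D array matching `geometry$shape`.
#' @param geometry an [image_geometry()].
#' @return a `seg_mask` object.
#' @export
seg_mask <- function(data, geometry) {
  data <- array(as.logical(data), dim = dim(data))
  if (!all(dim(data) == geometry$shape))
    stop("mask dimensions do not match geometry shape")
  structure(list(data = data, geometry = geometry), class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("seg_mask: %dx%dx%d, %d foreground voxels (%.2f cm^3)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], sum(x$data),
              sum(x$data) * prod(x$geometry$spacing) / 1000))
  invisible(x)
}

#' Analytic ellipsoid mask
#'
#' Foreground wherever the voxel CENTER lies inside the ellipsoid — the
#' discretization used for ground-truth masks, sharing the voxel-center
#' convention with [rasterize_mesh()].
#'
#' @param geometry an [image_geometry()].
#' @param center numeric length-3 ellipsoid center (mm).
#' @param radii numeric length-3 semi-axes (mm).
#' @return a `seg_mask`.
#' @export
ellipsoid_mask <- function(geometry, center, radii) {
  if (any(radii <= 0)) stop("radii must be strictly positive")
  cx <- geometry$origin[1] + (seq_len(geometry$shape[1]) - 1) * geometry$spacing[1]
  cy <- geometry$origin[2] + (seq_len(geometry$shape[2]) - 1) * geometry$spacing[2]
  cz <- geometry$origin[3] + (seq_len(geometry$shape[3]) - 1) * geometry$spacing[3]
  qx <- ((cx - center[1]) / radii[1])^2
  qy <- ((cy - center[2]) / radii[2])^2
  qz <- ((cz - center[3]) / radii[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  seg_mask(q < 1, geometry)
}

# Deterministic sub-voxel ray offset (fraction of spacing) that keeps
# z-parity rays clear of mesh vertices/edges without breaking the
# translation-consistency of rasterization (it shifts with the grid).
RAY_JITTER <- c(0.0317196261538, 0.0170423104572)

#' Rasterize a watertight mesh to a binary mask
#'
#' A voxel is foreground iff its CENTER is inside the closed surface, decided
#' by ray-crossing parity along +z columns: for every voxel column the mesh
#' triangles crossing the column's ray are collected, and voxels between
#' consecutive (entry, exit) crossings are filled. Deterministic; rays are
#' offset by a fixed sub-voxel amount so they never pass through mesh
#' vertices or edges.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param geometry the target [image_geometry()].
#' @return a `seg_mask` on `geometry`.
#' @export
rasterize_mesh <- function(mesh, geometry) {
  stop_if_not_watertight(mesh, "rasterize_mesh")
  sp <- geometry$spacing; or <- geometry$origin; sh <- geometry$shape
  # ray grid: column (ix, iy) passes through (cx, cy) slightly off-center
  jx <- RAY_JITTER[1] * sp[1]; jy <- RAY_JITTER[2] * sp[2]
  v <- mesh$vertices; f <- mesh$faces
  x1 <- v[f[, 1], 1]; y1 <- v[f[, 1], 2]
  x2 <- v[f[, 2], 1]; y2 <- v[f[, 2], 2]
  x3 <- v[f[, 3], 1]; y3 <- v[f[, 3], 2]
  # candidate columns per triangle from the 2D projected bounding box
  ix_lo <- pmax(ceiling((pmin(x1, x2, x3) - or[1] - jx) / sp[1]), 0)
  ix_hi <- pmin(floor((pmax(x1, x2, x3) - or[1] - jx) / sp[1]), sh[1] - 1)
  iy_lo <- pmax(ceiling((pmin(y1, y2, y3) - or[2] - jy) / sp[2]), 0)
  iy_hi <- pmin(floor((pmax(y1, y2, y3) - or[2] - jy) / sp[2]), sh[2] - 1)
  nx <- pmax(ix_hi - ix_lo + 1, 0); ny <- pmax(iy_hi - iy_lo + 1, 0)
  keep <- which(nx > 0 & ny > 0)
  mask <- array(FALSE, dim = sh)
  if (length(keep) > 0L) {
    ncell <- nx[keep] * ny[keep]
    tri <- rep(keep, ncell)
    # enumerate the (ix, iy) cells of each triangle's box
    off <- sequence(ncell) - 1L
    oy <- off %/% rep(nx[keep], ncell)
    ox <- off %% rep(nx[keep], ncell)
    ix <- rep(ix_lo[keep], ncell) + ox
    iy <- rep(iy_lo[keep], ncell) + oy
    cx <- or[1] + ix * sp[1] + jx
    cy <- or[2] + iy * sp[2] + jy
    # 2D barycentric point-in-triangle test at the ray position
    ax <- x1[tri]; ay <- y1[tri]
    bx <- x2[tri]; by <- y2[tri]
    ccx <- x3[tri]; ccy <- y3[tri]
    d <- (by - ccy) * (ax - ccx) + (ccx - bx) * (ay - ccy)
    w1 <- ((by - ccy) * (cx - ccx) + (ccx - bx) * (cy - ccy)) / d
    w2 <- ((ccy - ay) * (cx - ccx) + (ax - ccx) * (cy - ccy)) / d
    w3 <- 1 - w1 - w2
    inside <- is.finite(w1) & is.finite(w2) &
      w1 > 0 & w1 < 1 & w2 > 0 & w2 < 1 & w3 > 0 & w3 < 1
    if (any(inside)) {
      tri <- tri[inside]
      zc <- w1[inside] * v[f[tri, 1], 3] + w2[inside] * v[f[tri, 2], 3] +
        w3[inside] * v[f[tri, 3], 3]
      col <- ix[inside] + sh[1] * iy[inside]     # column id
      o <- order(col, zc)
      col <- col[o]; zc <- zc[o]
      runs <- rle(col)
      if (any(runs$lengths %% 2L != 0L))
        stop("rasterize_mesh: odd crossing parity; mesh is not a closed surface at ray resolution")
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      nzv <- sh[3]
      for (r in seq_along(runs$values)) {
        zz <- zc[starts[r]:ends[r]]
        cix <- runs$values[r] %% sh[1]
        ciy <- runs$values[r] %/% sh[1]
        for (p in seq(1L, length(zz), by = 2L)) {
          k_lo <- max(ceiling((zz[p] - or[3]) / sp[3]), 0)
          k_hi <- min(floor((zz[p + 1] - or[3]) / sp[3]), nzv - 1)
          if (k_hi >= k_lo)
            mask[cix + 1L, ciy + 1L, (k_lo + 1L):(k_hi + 1L)] <- TRUE
        }
      }
    }
  }
  seg_mask(mask, geometry)
}
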