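#' Dice overlap coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)` on voxel counts. The two masks must live on the
#' identical grid (shape, spacing, origin); a mismatch is an error, never a
#' silent resampling. Two empty masks have Dice 1 by convention (perfect
#' agreement about absence).
#'
#' @param maskA,maskB `seg_mask` objects on the same geometry.
#' @return Dice value in `[0, 1]`.
#' @export
dice_coefficient <- function(maskA, maskB) {
  stopifnot(inherits(maskA, "seg_mask"), inherits(maskB, "seg_mask"))
  if (!same_geometry(maskA$geometry, maskB$geometry))
    stop("mask geometries differ (shape/spacing/origin); refusing to compare")
  na <- sum(maskA$data); nb <- sum(maskB$data)
  if (na + nb == 0L) return(1.0)
  2 * sum(maskA$data & maskB$data) / (na + nb)
}

# Exact distances from points (N x 3) to the nearest point on any triangle
# of a mesh. Two stages keep this tractable without approximation: the
# nearest mesh VERTEX gives an upper bound for each point, and a triangle
# can only improve on that bound when one of its corners lies within
# (bound + longest mesh edge) of the point — every point of a triangle is
# within the longest edge of each of its corners. The exact point-triangle
# distance is evaluated only for those candidate pairs.
dist_points_to_mesh <- function(pts, mesh, chunk = 1024L) {
  v <- mesh$vertices; f <- mesh$faces
  np <- nrow(pts); nt <- nrow(f)
  if (np == 0L || nt == 0L) stop("empty input to surface distance")
  e_max <- sqrt(max(rowSums((v[f[, 1], ] - v[f[, 2], ])^2),
                    rowSums((v[f[, 2], ] - v[f[, 3], ])^2),
                    rowSums((v[f[, 3], ] - v[f[, 1], ])^2)))
  tv <- t(v)
  vnorm2 <- colSums(tv^2)
  out <- numeric(np)
  for (i0 in seq(1L, np, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, np)
    block <- pts[i0:i1, , drop = FALSE]
    m <- nrow(block)
    D2 <- outer(rowSums(block^2), vnorm2, `+`) - 2 * block %*% tv
    D2[D2 < 0] <- 0
    ub2 <- do.call(pmin, as.data.frame(D2))       # nearest-vertex bound^2
    thr2 <- (sqrt(ub2) + e_max)^2
    corner_min2 <- pmin(D2[, f[, 1], drop = FALSE],
                        D2[, f[, 2], drop = FALSE],
                        D2[, f[, 3], drop = FALSE])
    cand <- which(corner_min2 <= thr2, arr.ind = TRUE)
    best2 <- ub2
    if (nrow(cand) > 0L) {
      pi_ <- cand[, 1]; ti_ <- cand[, 2]
      d2 <- point_triangle_dist2(block[pi_, , drop = FALSE],
                                 v[f[ti_, 1], , drop = FALSE],
                                 v[f[ti_, 2], , drop = FALSE],
                                 v[f[ti_, 3], , drop = FALSE])
      agg <- tapply(d2, pi_, min)
      rows <- as.integer(names(agg))
      best2[rows] <- pmin(best2[rows], as.numeric(agg))
    }
    out[i0:i1] <- sqrt(best2)
  }
  out
}

point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  tt <- rowSums((p - a) * ab) / pmax(rowSums(ab^2), .Machine$double.xmin)
  tt <- pmin(pmax(tt, 0), 1)
  q <- a + tt * ab
  rowSums((p - q)^2)
}

point_triangle_dist2 <- function(p, a, b, c) {
  n <- cbind((b[, 2] - a[, 2]) * (c[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
  nn <- rowSums(n^2)
  h <- rowSums((p - a) * n)
  proj <- p - (h / pmax(nn, .Machine$double.xmin)) * n
  # barycentric test of the projection
  v0 <- c - a; v1 <- b - a; v2 <- proj - a
  d00 <- rowSums(v0^2); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1^2)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01^2
  u <- (d11 * d20 - d01 * d21) / pmax(den, .Machine$double.xmin)
  w <- (d00 * d21 - d01 * d20) / pmax(den, .Machine$double.xmin)
  inside <- u >= 0 & w >= 0 & (u + w) <= 1 & den > 0 & nn > 0
  d2 <- pmin(point_segment_dist2(p, a, b),
             point_segment_dist2(p, b, c),
             point_segment_dist2(p, c, a))
  d2[inside] <- (h[inside]^2) / nn[inside]
  d2
}

# Deterministic surface sampling: all vertices plus up to n_extra points
# drawn uniformly over the surface (area-weighted faces, uniform barycentric
# coordinates), using a private RNG stream so the caller's RNG is untouched.
sample_surface_points <- function(mesh, n_extra, seed) {
  v <- mesh$vertices; f <- mesh$faces
  pts <- v
  if (n_extra > 0L && nrow(f) > 0L) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    c <- v[f[, 3], , drop = FALSE]
    cr <- cbind((b[, 2] - a[, 2]) * (c[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c[, 2] - a[, 2]),
                (b[, 3] - a[, 3]) * (c[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c[, 3] - a[, 3]),
                (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
    area <- sqrt(rowSums(cr^2)) / 2
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fi <- sample.int(nrow(f), n_extra, replace = TRUE, prob = area)
    r1 <- sqrt(stats::runif(n_extra)); r2 <- stats::runif(n_extra)
    w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
    pts <- rbind(pts, w1 * a[fi, , drop = FALSE] + w2 * b[fi, , drop = FALSE] +
                   w3 * c[fi, , drop = FALSE])
  }
  pts
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Symmetric Hausdorff distance between two surfaces
#'
#' `max(h(A->B), h(B->A))` where `h` measures from point samples on one mesh
#' (all vertices plus area-uniform face samples up to `samples`) to the exact
#' nearest point on the other mesh's triangles. Deterministic for a given
#' sampling seed; the worst local surface error in mm.
#'
#' @param meshA,meshB non-empty [triangle_mesh()] objects.
#' @param samples number of extra surface samples per mesh beyond its
#'   vertices (default 1000).
#' @param seed sampling seed (default 42); the caller's RNG state is
#'   preserved.
#' @return Hausdorff distance in mm.
#' @export
hausdorff_distance <- function(meshA, meshB, samples = 1000L, seed = 42L) {
  if (nrow(meshA$vertices) == 0L || nrow(meshB$vertices) == 0L)
    stop("empty mesh in Hausdorff computation")
  pa <- sample_surface_points(meshA, samples, seed)
  pb <- sample_surface_points(meshB, samples, seed + 1L)
  max(max(dist_points_to_mesh(pa, meshB)),
      max(dist_points_to_mesh(pb, meshA)))
}

#' Mask-based symmetric Hausdorff distance
#'
#' Cross-check variant on voxel grids: distance between the surface-voxel
#' sets (foreground voxels with at least one 6-neighbour background voxel) of
#' two masks, measured center-to-center.
#'
#' @param maskA,maskB `seg_mask` objects on the same geometry.
#' @return Hausdorff distance in mm.
#' @export
hausdorff_mask <- function(maskA, maskB) {
  stopifnot(inherits(maskA, "seg_mask"), inherits(maskB, "seg_mask"))
  if (!same_geometry(maskA$geometry, maskB$geometry))
    stop("mask geometries differ (shape/spacing/origin); refusing to compare")
  sa <- mask_surface_voxels(maskA); sb <- mask_surface_voxels(maskB)
  if (nrow(sa) == 0L || nrow(sb) == 0L)
    stop("empty mask in Hausdorff computation")
  max(directed_point_hausdorff(sa, sb), directed_point_hausdorff(sb, sa))
}

mask_surface_voxels <- function(mask) {
  d <- mask$data
  sh <- dim(d)
  pad <- array(FALSE, dim = sh + 2L)
  pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- d
  core <- pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)]
  nb <- pad[1:sh[1], 2:(sh[2] + 1), 2:(sh[3] + 1)] &
    pad[3:(sh[1] + 2), 2:(sh[2] + 1), 2:(sh[3] + 1)] &
    pad[2:(sh[1] + 1), 1:sh[2], 2:(sh[3] + 1)] &
    pad[2:(sh[1] + 1), 3:(sh[2] + 2), 2:(sh[3] + 1)] &
    pad[2:(sh[1] + 1), 2:(sh[2] + 1), 1:sh[3]] &
    pad[2:(sh[1] + 1), 2:(sh[2] + 1), 3:(sh[3] + 2)]
  surf <- which(core & !nb, arr.ind = TRUE) - 1L
  sweep(sweep(surf, 2, mask$geometry$spacing, `*`), 2, mask$geometry$origin, `+`)
}

directed_point_hausdorff <- function(pa, pb, chunk = 4096L) {
  worst <- 0
  tb <- t(pb)
  for (i0 in seq(1L, nrow(pa), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(pa))
    block <- pa[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(block^2), colSums(tb^2), `+`) - 2 * block %*% tb
    worst <- max(worst, max(sqrt(pmax(apply(d2, 1, min), 0))))
  }
  worst
}

#' Segmentation quality report
#'
#' Case-level evaluation table: initial and final Dice against a ground-truth
#' mask, number of interactions, and final surface Hausdorff distance.
#'
#' @param case_id character label for the case.
#' @param initial_mesh,final_mesh [triangle_mesh()] segmentations.
#' @param gt_mask ground-truth `seg_mask` (also fixes the Dice geometry).
#' @param gt_mesh optional ground-truth mesh for the Hausdorff column.
#' @param interactions number of correction interactions performed.
#' @return one-row data.frame with columns `case`, `initial_dice`,
#'   `final_dice`, `interactions`, `hausdorff_mm`.
#' @export
metrics_report <- function(case_id, initial_mesh, final_mesh, gt_mask,
                           gt_mesh = NULL, interactions = NA_integer_) {
  g <- gt_mask$geometry
  di <- dice_coefficient(rasterize_mesh(initial_mesh, g), gt_mask)
  df <- dice_coefficient(rasterize_mesh(final_mesh, g), gt_mask)
  hd <- if (is.null(gt_mesh)) NA_real_ else
    hausdorff_distance(final_mesh, gt_mesh)
  data.frame(case = case_id, initial_dice = di, final_dice = df,
             interactions = as.integer(interactions), hausdorff_mm = hd,
             stringsAsFactors = FALSE)
}

#' Write a metrics report
#'
#' @param report data.frame from [metrics_report()] (rows may be stacked).
#' @param path output path; `.json` writes JSON, anything else a
#'   tab-separated table.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, digits = I(17), dataframe = "rows")
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
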