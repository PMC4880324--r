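# Iso-surface extraction from a binary label volume by marching tetrahedra.
# Every grid cell is split into the six Kuhn tetrahedra around its main
# diagonal (a decomposition that is face-consistent across neighbouring
# cells, so the extracted surface is crack-free), and the 0.5 level set
# between background (0) and foreground (1) is triangulated inside each
# tetrahedron. On binary data every surface vertex is a grid-edge midpoint;
# the volume is zero-padded by one voxel so border-touching objects close.

# Kuhn tetrahedra of the unit cell; corner id = i + 2j + 4k (0-based)
TET_SPLIT <- matrix(c(
  0L, 1L, 3L, 7L,
  0L, 1L, 5L, 7L,
  0L, 4L, 5L, 7L,
  0L, 2L, 3L, 7L,
  0L, 2L, 6L, 7L,
  0L, 4L, 6L, 7L), ncol = 4L, byrow = TRUE)

CELL_CORNERS <- cbind(i = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
                      j = c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L),
                      k = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

EDGE_KEY_BASE <- 2^21  # corner linear indices stay far below this

#' Extract the surface of a binary mask
#'
#' Marching-tetrahedra iso-surface at level 0.5 between background and
#' foreground, returning a watertight, outward-oriented triangle mesh in
#' world mm.
#'
#' @param mask a `seg_mask`.
#' @return a [triangle_mesh()].
#' @export
mask_to_mesh <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  if (!any(mask$data)) stop("empty label volume: no foreground voxels")
  g <- mask$geometry
  sh <- g$shape
  n <- sh + 2L
  fld <- array(0, dim = n)
  fld[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- as.numeric(mask$data)

  ncell <- n - 1L
  ci <- arrayInd(seq_len(prod(ncell)), ncell)
  corner_lin <- matrix(0, nrow(ci), 8L)   # linear index in padded grid
  corner_val <- matrix(0, nrow(ci), 8L)
  for (c8 in 1:8) {
    ii <- ci[, 1] + CELL_CORNERS[c8, 1]
    jj <- ci[, 2] + CELL_CORNERS[c8, 2]
    kk <- ci[, 3] + CELL_CORNERS[c8, 3]
    lin <- ii + n[1] * (jj - 1L) + n[1] * n[2] * (kk - 1L)
    corner_lin[, c8] <- lin
    corner_val[, c8] <- fld[lin]
  }
  active <- which(do.call(pmin, as.data.frame(corner_val)) < 0.5 &
                    do.call(pmax, as.data.frame(corner_val)) > 0.5)
  if (length(active) == 0L) stop("empty label volume: no iso-surface")
  corner_lin <- corner_lin[active, , drop = FALSE]
  corner_val <- corner_val[active, , drop = FALSE]

  # world-scaled corner positions, needed only for orientation tests
  corner_pos <- function(lin) {
    p <- arrayInd(lin, n)
    sweep(p, 2, g$spacing, `*`)
  }

  tris <- list()
  for (tet in seq_len(nrow(TET_SPLIT))) {
    crn <- TET_SPLIT[tet, ] + 1L
    lin4 <- corner_lin[, crn, drop = FALSE]
    ins4 <- corner_val[, crn, drop = FALSE] > 0.5
    pattern <- ins4 %*% c(1L, 2L, 4L, 8L)
    for (pat in 1:14) {
      rows <- which(pattern == pat)
      if (length(rows) == 0L) next
      ins <- which(bitwAnd(pat, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      tris[[length(tris) + 1L]] <-
        tet_case_triangles(lin4[rows, , drop = FALSE], ins, outs, corner_pos)
    }
  }
  tv <- do.call(rbind, tris)

  edge_keys <- c(tv[, 1], tv[, 2], tv[, 3])
  uk <- unique(edge_keys)
  vid <- match(edge_keys, uk)
  nt <- nrow(tv)
  faces <- cbind(vid[seq_len(nt)], vid[nt + seq_len(nt)],
                 vid[2L * nt + seq_len(nt)])
  # vertex = midpoint of the crossing grid edge, in world mm
  ka <- ((uk - 1) %% EDGE_KEY_BASE) + 1
  kb <- ((uk - 1) %/% EDGE_KEY_BASE) + 1
  pa <- arrayInd(ka, n); pb <- arrayInd(kb, n)
  mid <- (pa + pb) / 2
  verts <- sweep(sweep(mid - 2, 2, g$spacing, `*`), 2, g$origin, `+`)
  m <- triangle_mesh(verts, faces)
  if (!is_watertight(m))
    stop("internal error: extracted iso-surface is not watertight")
  m
}

# Triangles of one (tetrahedron, inside-pattern) case over many cells at
# once. Vertices are crossing edges encoded inside->outside as
# key = lin_in + (lin_out - 1) * EDGE_KEY_BASE; winding is fixed so normals
# point from foreground to background.
tet_case_triangles <- function(lin4, ins, outs, corner_pos) {
  ek <- function(a, b) lin4[, a] + (lin4[, b] - 1) * EDGE_KEY_BASE
  mid <- function(a, b) (corner_pos(lin4[, a]) + corner_pos(lin4[, b])) / 2
  orient <- function(p1, p2, p3, dir) {
    nrm <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) - (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
                 (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) - (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
                 (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) - (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
    rowSums(nrm * dir) < 0
  }
  if (length(ins) == 1L) {
    a <- ek(ins, outs[1]); b <- ek(ins, outs[2]); cc <- ek(ins, outs[3])
    p1 <- mid(ins, outs[1]); p2 <- mid(ins, outs[2]); p3 <- mid(ins, outs[3])
    dir <- (p1 + p2 + p3) / 3 - corner_pos(lin4[, ins])
    tri <- cbind(a, b, cc)
    flip <- orient(p1, p2, p3, dir)
    tri[flip, ] <- tri[flip, c(1L, 3L, 2L), drop = FALSE]
    tri
  } else if (length(ins) == 3L) {
    a <- ek(ins[1], outs); b <- ek(ins[2], outs); cc <- ek(ins[3], outs)
    p1 <- mid(ins[1], outs); p2 <- mid(ins[2], outs); p3 <- mid(ins[3], outs)
    dir <- corner_pos(lin4[, outs]) - (p1 + p2 + p3) / 3
    tri <- cbind(a, b, cc)
    flip <- orient(p1, p2, p3, dir)
    tri[flip, ] <- tri[flip, c(1L, 3L, 2L), drop = FALSE]
    tri
  } else {
    # two inside, two outside: the four crossing edges form a quad
    a <- ek(ins[1], outs[1]); b <- ek(ins[1], outs[2])
    cc <- ek(ins[2], outs[2]); d <- ek(ins[2], outs[1])
    pa <- mid(ins[1], outs[1]); pb <- mid(ins[1], outs[2])
    pc <- mid(ins[2], outs[2]); pd <- mid(ins[2], outs[1])
    dir <- (corner_pos(lin4[, outs[1]]) + corner_pos(lin4[, outs[2]]) -
              corner_pos(lin4[, ins[1]]) - corner_pos(lin4[, ins[2]])) / 2
    t1 <- cbind(a, b, cc); t2 <- cbind(a, cc, d)
    f1 <- orient(pa, pb, pc, dir)
    f2 <- orient(pa, pc, pd, dir)
    t1[f1, ] <- t1[f1, c(1L, 3L, 2L), drop = FALSE]
    t2[f2, ] <- t2[f2, c(1L, 3L, 2L), drop = FALSE]
    rbind(t1, t2)
  }
}

#' Load a segmentation as a surface mesh
#'
#' Mesh files (`.ply`, `.off`, `.stl`) load directly; label volumes
#' (`.nii[.gz]`, `.mhd`, `.mha`) are surfaced by iso-surface extraction at
#' 0.5 between background and foreground ([mask_to_mesh()]), producing a
#' watertight mesh in world mm.
#'
#' @param path segmentation file.
#' @return a [triangle_mesh()].
#' @export
load_segmentation <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("ply", "off", "stl")) read_mesh(path)
  else if (ext %in% c("nii", "mhd", "mha")) mask_to_mesh(read_label_volume(path))
  else stop(sprintf("unsupported segmentation format: %s", path))
}
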