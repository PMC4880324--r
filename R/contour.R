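#' Image geometry
#'
#' The coordinate bridge between voxels, slice planes, and meshes: voxel grid
#' shape, isotropic-or-not spacing in mm, and the world position of the
#' CENTER of voxel (0,0,0). Orientation is identity (axis-aligned volumes
#' only); world position of voxel `(i,j,k)` (0-based) is
#' `origin + c(i,j,k) * spacing`.
#'
#' @param shape integer length-3 voxel counts (nx, ny, nz).
#' @param spacing numeric length-3 mm per voxel, strictly positive.
#' @param origin numeric length-3 world position (mm) of voxel (0,0,0).
#' @return an `image_geometry` object.
#' @export
image_geometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive counts")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be strictly positive")
  if (length(origin) != 3L || !all(is.finite(origin))) stop("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("image_geometry: %dx%dx%d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

#' Slice plane
#'
#' Either a canonical image plane (`axis` = "sagittal" (x), "coronal" (y) or
#' "axial" (z) plus a 0-based voxel `index` along that axis) or an arbitrary
#' plane given by a point and unit normal.
#'
#' @param axis one of "axial", "coronal", "sagittal" (canonical form).
#' @param index 0-based voxel index along the axis (canonical form).
#' @param point,normal numeric length-3 world point and normal (arbitrary
#'   form); the normal is normalized to unit length.
#' @return a `slice_plane` object.
#' @export
slice_plane <- function(axis = NULL, index = NULL, point = NULL, normal = NULL) {
  if (!is.null(axis)) {
    axis <- match.arg(axis, c("axial", "coronal", "sagittal"))
    index <- as.integer(index)
    if (length(index) != 1L || is.na(index) || index < 0L)
      stop("index must be a single non-negative voxel index")
    structure(list(kind = "canonical", axis = axis, index = index),
              class = "slice_plane")
  } else {
    point <- as.numeric(point); normal <- as.numeric(normal)
    if (length(point) != 3L || length(normal) != 3L ||
          !all(is.finite(c(point, normal))))
      stop("point and normal must be finite length-3 vectors")
    nn <- sqrt(sum(normal^2))
    if (nn == 0) stop("normal must be nonzero")
    structure(list(kind = "arbitrary", point = point, normal = normal / nn),
              class = "slice_plane")
  }
}

canonical_axis_index <- function(axis) {
  switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
}

# Resolved plane frame: world point, unit normal, and an orthonormal in-plane
# basis (e1, e2). Canonical planes use the two remaining world axes in
# (x,y,z) order so in-plane coordinates are plain world coordinates along
# those axes; arbitrary planes use a deterministic basis built from the
# normal (smallest-|component| world axis crossed with the normal).
plane_frame <- function(plane, geometry = NULL) {
  if (plane$kind == "canonical") {
    ax <- canonical_axis_index(plane$axis)
    if (is.null(geometry))
      stop("canonical slice planes need an image_geometry to resolve the level")
    if (plane$index >= geometry$shape[ax])
      stop(sprintf("slice index %d out of range for axis %s (shape %d)",
                   plane$index, plane$axis, geometry$shape[ax]))
    level <- geometry$origin[ax] + plane$index * geometry$spacing[ax]
    n <- numeric(3); n[ax] <- 1
    inplane <- setdiff(1:3, ax)
    e1 <- numeric(3); e1[inplane[1]] <- 1
    e2 <- numeric(3); e2[inplane[2]] <- 1
    p0 <- numeric(3); p0[ax] <- level
    list(point = p0, normal = n, e1 = e1, e2 = e2)
  } else {
    n <- plane$normal
    a <- numeric(3); a[which.min(abs(n))] <- 1
    e1 <- c(a[2] * n[3] - a[3] * n[2],
            a[3] * n[1] - a[1] * n[3],
            a[1] * n[2] - a[2] * n[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    list(point = plane$point, normal = n, e1 = e1, e2 = e2)
  }
}

plane_project_2d <- function(frame, pts) {
  d <- sweep(pts, 2, frame$point, `-`)
  cbind(d %*% frame$e1, d %*% frame$e2)
}

plane_lift_3d <- function(frame, pts2d) {
  sweep(pts2d[, 1, drop = FALSE] %*% rbind(frame$e1) +
          pts2d[, 2, drop = FALSE] %*% rbind(frame$e2),
        2, frame$point, `+`)
}

# endpoints closer than this are the same contour node
LINK_TOL <- 1e-6

#' Intersect a mesh with a slice plane
#'
#' Every triangle crossing the plane contributes a segment whose endpoints
#' are linear interpolations along the two crossing edges; segments sharing a
#' mesh edge are linked into polylines. A closed watertight mesh yields only
#' closed polylines. A plane missing the mesh gives an empty contour (not an
#' error).
#'
#' @param mesh a [triangle_mesh()].
#' @param plane a [slice_plane()].
#' @param geometry an [image_geometry()] (required for canonical planes).
#' @return a `mesh_contour`: list of polylines, each with `world` (`P x 3`
#'   mm), `plane2d` (`P x 2` in-plane mm), `closed` flag, and `edges`
#'   (the source mesh edge of each point); carries the resolved plane frame.
#' @export
extract_contour <- function(mesh, plane, geometry = NULL) {
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  frame <- plane_frame(plane, geometry)
  v <- mesh$vertices
  sd <- as.numeric(sweep(v, 2, frame$point, `-`) %*% frame$normal)
  # nudge exact-zero vertices off the plane so every crossing is transversal
  sd[sd == 0] <- LINK_TOL * 1e-3
  f <- mesh$faces
  s1 <- sd[f[, 1]]; s2 <- sd[f[, 2]]; s3 <- sd[f[, 3]]
  crossing <- which((pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0))
  if (length(crossing) == 0L)
    return(empty_contour(plane, frame))

  seg_pts <- vector("list", 2L)
  seg_edge <- vector("list", 2L)
  for (corner in 1:2) {
    seg_pts[[corner]] <- matrix(0, length(crossing), 3L)
    seg_edge[[corner]] <- character(length(crossing))
  }
  slot <- integer(length(crossing))  # how many endpoints found so far
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (ep in edge_pairs) {
    a <- f[crossing, ep[1]]; b <- f[crossing, ep[2]]
    da <- sd[a]; db <- sd[b]
    hit <- which(da * db < 0)
    if (length(hit) == 0L) next
    tt <- da[hit] / (da[hit] - db[hit])
    pts <- v[a[hit], , drop = FALSE] +
      tt * (v[b[hit], , drop = FALSE] - v[a[hit], , drop = FALSE])
    ekey <- paste(pmin(a[hit], b[hit]), pmax(a[hit], b[hit]))
    # each triangle crosses at most once per edge-pair pass, so the
    # endpoint slot assignment vectorizes
    cur <- slot[hit]
    for (sl in 1:2) {
      take <- cur == (sl - 1L)
      if (any(take)) {
        seg_pts[[sl]][hit[take], ] <- pts[take, , drop = FALSE]
        seg_edge[[sl]][hit[take]] <- ekey[take]
      }
    }
    slot[hit] <- cur + 1L
  }
  ok <- slot == 2L
  p1 <- seg_pts[[1]][ok, , drop = FALSE]; e1 <- seg_edge[[1]][ok]
  p2 <- seg_pts[[2]][ok, , drop = FALSE]; e2 <- seg_edge[[2]][ok]
  polys <- link_segments(p1, p2, e1, e2)
  contour_from_polylines(polys, plane, frame)
}

empty_contour <- function(plane, frame) {
  structure(list(polylines = list(), plane = plane, frame = frame),
            class = "mesh_contour")
}

# Chain segments into polylines by walking shared mesh edges.
link_segments <- function(p1, p2, e1, e2) {
  ns <- nrow(p1)
  used <- rep(FALSE, ns)
  # adjacency: edge key -> segment indices (each interior edge touches 2 segs)
  adj <- split(rep(seq_len(ns), 2L), c(e1, e2))
  polys <- list()
  for (start in seq_len(ns)) {
    if (used[start]) next
    # walk forward from `start` along e2 side
    idx <- start; enter <- e1[start]
    pts <- list(p1[start, ]); edges <- c(e1[start])
    closed <- FALSE
    repeat {
      used[idx] <- TRUE
      exit <- if (e1[idx] == enter) e2[idx] else e1[idx]
      pts[[length(pts) + 1L]] <- if (e1[idx] == enter) p2[idx, ] else p1[idx, ]
      edges <- c(edges, exit)
      nxt <- setdiff(adj[[exit]], idx)
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) {
        # either closed back to start, or an open chain (non-watertight mesh)
        closed <- identical(exit, edges[1L]) ||
          sum(abs(pts[[length(pts)]] - pts[[1L]])) < LINK_TOL
        break
      }
      idx <- nxt[1L]; enter <- exit
    }
    pm <- do.call(rbind, pts)
    if (closed && nrow(pm) > 1L) {
      pm <- pm[-nrow(pm), , drop = FALSE]  # first=last topologically, stored once
      edges <- edges[-length(edges)]
    }
    polys[[length(polys) + 1L]] <- list(points = pm, edges = edges,
                                        closed = closed)
  }
  polys
}

contour_from_polylines <- function(polys, plane, frame) {
  polylines <- lapply(polys, function(p) {
    list(world = p$points,
         plane2d = plane_project_2d(frame, p$points),
         edges = p$edges,
         closed = p$closed)
  })
  structure(list(polylines = polylines, plane = plane, frame = frame),
            class = "mesh_contour")
}

#' @export
print.mesh_contour <- function(x, ...) {
  np <- length(x$polylines)
  cat(sprintf("mesh_contour: %d polyline(s)%s\n", np,
              if (np) sprintf(", %s points",
                              paste(vapply(x$polylines, function(p)
                                nrow(p$world), numeric(1)), collapse = "+"))
              else ""))
  invisible(x)
}

#' All contour points as matrices
#' @param contour a `mesh_contour`.
#' @return list with `world` (`N x 3`) and `plane2d` (`N x 2`) matrices.
#' @export
contour_points <- function(contour) {
  if (length(contour$polylines) == 0L)
    return(list(world = matrix(0, 0, 3), plane2d = matrix(0, 0, 2)))
  list(world = do.call(rbind, lapply(contour$polylines, `[[`, "world")),
       plane2d = do.call(rbind, lapply(contour$polylines, `[[`, "plane2d")))
}

#' Lift a 2D in-plane drag to world coordinates
#'
#' Maps the drag's 2D start and end points on a slice to world coordinates
#' through the plane's orthonormal in-plane basis. The displacement is
#' length-preserving and lies exactly in the plane.
#'
#' @param plane a [slice_plane()].
#' @param geometry an [image_geometry()] (for canonical planes).
#' @param p_start,p_end numeric length-2 in-plane mm coordinates.
#' @return list with `start` (world mm), `end` (world mm) and
#'   `displacement` (`end - start`).
#' @export
lift_drag <- function(plane, geometry, p_start, p_end) {
  frame <- plane_frame(plane, geometry)
  w <- plane_lift_3d(frame, rbind(as.numeric(p_start), as.numeric(p_end)))
  list(start = w[1, ], end = w[2, ], displacement = w[2, ] - w[1, ])
}

#' Pick the mesh vertex under a drag start point
#'
#' Finds the contour point nearest the cursor, then returns the mesh vertex
#' nearest that contour point (Euclidean world distance); the drag constraint
#' is attached to an existing embedded vertex, never an interpolated edge
#' point. Ties break to the lowest vertex index.
#'
#' @param mesh a [triangle_mesh()].
#' @param contour a non-empty `mesh_contour` on the drag's plane.
#' @param p_start numeric length-3 world point of the drag start.
#' @return 1-based vertex index.
#' @export
pick_vertex <- function(mesh, contour, p_start) {
  cp <- contour_points(contour)$world
  if (nrow(cp) == 0L) stop("no contour under cursor")
  d2c <- colSums((t(cp) - as.numeric(p_start))^2)
  target <- cp[which.min(d2c), ]
  d2v <- colSums((t(mesh$vertices) - target)^2)
  which.min(d2v)  # which.min breaks ties at the lowest index
}
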