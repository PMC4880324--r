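test_that("plane-sphere contours are closed circles of the analytic radius", {
  sph <- ellipsoid_mesh(c(0, 0, 0), c(1, 1, 1), 4L)
  chordal_tol <- 0.01  # max sagitta of a subdiv-4 icosphere chord

  ct0 <- extract_contour(sph, slice_plane(point = c(0, 0, 0), normal = c(0, 0, 1)))
  expect_length(ct0$polylines, 1)
  expect_true(ct0$polylines[[1]]$closed)
  r0 <- sqrt(rowSums(contour_points(ct0)$world[, 1:2]^2))
  expect_true(all(abs(r0 - 1) < chordal_tol))

  # off-center slice: circle of radius sqrt(1 - 0.25)
  ct <- extract_contour(sph, slice_plane(point = c(0, 0, 0.5), normal = c(0, 0, 1)))
  expect_length(ct$polylines, 1)
  r <- sqrt(rowSums(contour_points(ct)$world[, 1:2]^2))
  expect_true(all(abs(r - sqrt(0.75)) < chordal_tol))

  # plane outside the sphere: empty contour, not an error
  far <- extract_contour(sph, slice_plane(point = c(0, 0, 2), normal = c(0, 0, 1)))
  expect_length(far$polylines, 0)
})

test_that("contour points lie on the slice plane and on their source edges", {
  sph <- test_sphere()
  set.seed(61)
  for (trial in 1:20) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    lvl <- runif(1, -6, 6)
    pl <- slice_plane(point = lvl * nrm, normal = nrm)
    ct <- extract_contour(sph, pl)
    expect_gt(length(ct$polylines), 0)
    expect_true(all(vapply(ct$polylines, `[[`, TRUE, "closed")))
    pts <- contour_points(ct)$world
    # on-plane to 1e-9 mm
    expect_lt(max(abs(sweep(pts, 2, lvl * nrm, `-`) %*% nrm)), 1e-9)
    # each point on its source mesh edge (within 1e-9 of the segment)
    for (poly in ct$polylines) {
      ends <- do.call(rbind, strsplit(poly$edges, " "))
      a <- sph$vertices[as.integer(ends[, 1]), , drop = FALSE]
      b <- sph$vertices[as.integer(ends[, 2]), , drop = FALSE]
      ab <- b - a
      tt <- rowSums((poly$world - a) * ab) / rowSums(ab^2)
      expect_true(all(tt > -1e-9 & tt < 1 + 1e-9))
      expect_lt(max(abs(poly$world - (a + tt * ab))), 1e-9)
    }
  }
})

test_that("canonical planes use image geometry and world-axis 2D bases", {
  geom <- image_geometry(c(32, 32, 32), c(0.5, 0.5, 0.5), c(-7.75, -7.75, -7.75))
  sph <- ellipsoid_mesh(c(0, 0, 0), c(5, 5, 5), 3L)
  # axial slice at voxel index 15 -> world z = -7.75 + 15*0.5 = -0.25
  ct <- extract_contour(sph, slice_plane(axis = "axial", index = 15L), geom)
  z <- contour_points(ct)$world[, 3]
  expect_true(all(abs(z - (-0.25)) < 1e-9))
  # in-plane coordinates equal the world x/y coordinates
  p <- contour_points(ct)
  expect_equal(p$plane2d[, 1], p$world[, 1])
  expect_equal(p$plane2d[, 2], p$world[, 2])
  expect_error(extract_contour(sph, slice_plane(axis = "axial", index = 99L), geom),
               "out of range")
})

test_that("lift_drag maps in-plane displacements isometrically into the plane", {
  geom <- test_geometry()
  pl <- slice_plane(axis = "coronal", index = 10L)
  same <- lift_drag(pl, geom, c(1.2, -3), c(1.2, -3))
  expect_equal(same$displacement, c(0, 0, 0))

  lifted <- lift_drag(pl, geom, c(0, 0), c(3, 4))
  expect_equal(sqrt(sum(lifted$displacement^2)), 5)     # isometric
  expect_equal(lifted$displacement[2], 0)               # no normal component

  set.seed(62)
  nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
  pla <- slice_plane(point = c(1, 2, 3), normal = nrm)
  a <- runif(2, -5, 5); b <- runif(2, -5, 5)
  la <- lift_drag(pla, NULL, a, b)
  expect_equal(sqrt(sum(la$displacement^2)), sqrt(sum((b - a)^2)))
  expect_lt(abs(sum(la$displacement * nrm)), 1e-12)
})

test_that("pick_vertex snaps to the nearest mesh vertex with index tie-break", {
  sph <- test_sphere()
  pl <- slice_plane(point = c(0, 0, 0), normal = c(0, 0, 1))
  ct <- extract_contour(sph, pl)

  # a vertex lying on the plane is picked exactly
  on_plane <- which(abs(sph$vertices[, 3]) < 1e-9)
  expect_gt(length(on_plane), 0)
  vid <- on_plane[1]
  expect_equal(pick_vertex(sph, ct, sph$vertices[vid, ]), vid)

  # brute-force nearest-vertex oracle from random cursor positions
  set.seed(63)
  edge_len <- mean(sqrt(rowSums((sph$vertices[sph$faces[, 1], ] -
                                   sph$vertices[sph$faces[, 2], ])^2)))
  for (trial in 1:20) {
    th <- runif(1, 0, 2 * pi)
    cursor <- c(10.3 * cos(th), 10.3 * sin(th), 0.05)
    got <- pick_vertex(sph, ct, cursor)
    expect_lt(sqrt(sum((sph$vertices[got, ] - cursor)^2)), 2 * edge_len)
  }

  # equidistant tie resolves to the lower index: the contour point
  # (-0.5, 0, 0) is equidistant from vertices 1 and 3
  tri <- triangle_mesh(rbind(c(-1, 0, 1), c(1, 0, 1), c(0, 0, -1)),
                       rbind(c(1, 2, 3)))
  ctt <- extract_contour(tri, slice_plane(point = c(0, 0, 0), normal = c(0, 0, 1)))
  expect_equal(pick_vertex(tri, ctt, c(-0.2, 0, 0)), 1L)

  empty <- extract_contour(sph, slice_plane(point = c(0, 0, 99), normal = c(0, 0, 1)))
  expect_error(pick_vertex(sph, empty, c(0, 0, 0)), "no contour")
})

test_that("watertight meshes produce only closed polylines on random planes", {
  sph <- test_sphere(subdiv = 2L)
  set.seed(64)
  for (trial in 1:100) {
    nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
    pl <- slice_plane(point = rnorm(3, sd = 3), normal = nrm)
    ct <- extract_contour(sph, pl)
    if (length(ct$polylines) > 0)
      expect_true(all(vapply(ct$polylines, `[[`, TRUE, "closed")))
  }
})

test_that("rasterization reproduces analytic volumes and translation consistency", {
  sph <- test_sphere(r = 10, subdiv = 4L)
  geom <- test_geometry()
  mask <- rasterize_mesh(sph, geom)
  vol <- sum(mask$data) * prod(geom$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)

  # agreement with the analytic ball discretization
  amask <- ellipsoid_mask(geom, c(0, 0, 0), c(10, 10, 10))
  expect_gte(dice_coefficient(mask, amask), 0.98)

  # mesh entirely outside the volume -> all-zero mask
  far <- translate_mesh(sph, c(100, 0, 0))
  expect_equal(sum(rasterize_mesh(far, geom)$data), 0)

  # shifting mesh and origin together yields the identical mask
  shift <- c(4, -8, 2.5)
  geom2 <- image_geometry(geom$shape, geom$spacing, geom$origin + shift)
  mask2 <- rasterize_mesh(translate_mesh(sph, shift), geom2)
  expect_identical(mask2$data, mask$data)

  # open surfaces are rejected with the boundary-edge count
  open_mesh <- triangle_mesh(sph$vertices, sph$faces[-1, ])
  expect_error(rasterize_mesh(open_mesh, geom), "watertight")
})
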