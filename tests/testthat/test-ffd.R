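test_that("Bernstein weights match direct binomial expansion and sum to one", {
  # degree-1 midpoint: all eight weights equal by symmetry
  w <- bernstein_weights(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_equal(dim(w), c(2L, 2L, 2L))
  expect_equal(as.numeric(w), rep(0.125, 8))

  # endpoint property: all mass on the first control point
  w0 <- bernstein_weights(c(5, 5, 5), c(0, 0, 0))
  expect_equal(w0[1, 1, 1], 1)
  expect_equal(sum(w0), 1)
  expect_equal(max(abs(w0[-1])), 0)

  # mixed-degree case against the independent per-axis oracle
  w2 <- bernstein_weights(c(2, 1, 1), c(0.25, 0.5, 0.5))
  for (i in 0:2) for (j in 0:1) for (k in 0:1) {
    expect_equal(w2[i + 1, j + 1, k + 1],
                 bernstein_1d_oracle(2, i, 0.25) *
                   bernstein_1d_oracle(1, j, 0.5) *
                   bernstein_1d_oracle(1, k, 0.5))
  }
  expect_equal(as.numeric(w2[, 1, 1]), c(0.5625, 0.375, 0.0625) * 0.25)

  # partition of unity over random coordinates
  set.seed(11)
  co <- matrix(runif(3000), 1000, 3)
  W <- bernstein_weights(c(5, 5, 5), co)
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)

  expect_error(bernstein_weights(c(5, 5, 5), c(NaN, 0, 0)), "finite")
})

test_that("global grid fitting covers the mesh with the requested padding", {
  cube <- unit_cube_mesh()
  g0 <- fit_global_grid(cube, c(5, 5, 5), padding = 0)
  expect_equal(g0$origin, c(0, 0, 0))
  expect_equal(diag(g0$axes), c(1, 1, 1))
  expect_equal(n_control_points(g0), 216L)

  g1 <- fit_global_grid(cube, c(5, 5, 5), padding = 0.1)
  expect_equal(g1$origin, c(-0.1, -0.1, -0.1))
  expect_equal(diag(g1$axes), c(1.2, 1.2, 1.2))

  co <- embed_mesh(cube, g1)
  expect_true(all(co$embedded))
  expect_true(all(co$coords >= 0 & co$coords <= 1))

  flat <- point_cloud_mesh(cbind(runif(5), runif(5), 0.7))
  expect_error(fit_global_grid(flat, c(5, 5, 5)), "axis z")
})

test_that("local grid keeps the control-point count and recovers the global fit", {
  gl <- fit_local_grid(c(0, 0, 0), c(2, 2, 2), c(5, 5, 5))
  expect_equal(gl$origin, c(-1, -1, -1))
  expect_equal(n_control_points(gl), 216L)

  # same degrees as global mode: identical count, finer spacing
  sph <- test_sphere()
  gg <- fit_global_grid(sph, c(5, 5, 5), 0.05)
  expect_equal(n_control_points(gl), n_control_points(gg))
  expect_lt(max(abs(gl$axes)), max(abs(gg$axes)))

  # consistency: local grid sized/centered on the bounding box == global, pad 0
  bb <- mesh_bounds(sph)
  gc <- fit_local_grid((bb$min + bb$max) / 2, bb$max - bb$min, c(5, 5, 5))
  g0 <- fit_global_grid(sph, c(5, 5, 5), padding = 0)
  expect_equal(gc$origin, g0$origin)
  expect_equal(gc$control_points, g0$control_points)

  expect_error(fit_local_grid(c(0, 0, 0), c(1, 0, 1)), "positive")
})

test_that("embedding inverts the lattice frame, including sheared frames", {
  g <- control_grid(c(1, 2, 3), diag(c(2, 3, 4)), c(2, 2, 2))
  corners <- point_cloud_mesh(rbind(c(1, 2, 3), c(1, 2, 3) + c(2, 3, 4)))
  co <- embed_mesh(corners, g)
  expect_equal(co$coords[1, ], c(0, 0, 0))
  expect_equal(co$coords[2, ], c(1, 1, 1))
  expect_true(all(co$embedded))

  # sheared (non-orthogonal) frame: recompose X0 + sS + tT + uU == x
  set.seed(21)
  axes <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  gs <- control_grid(c(-1, 0.5, 2), axes, c(3, 3, 3))
  x <- sweep(matrix(runif(300), 100, 3) %*% t(axes), 2, gs$origin, `+`)
  cos_ <- embed_mesh(point_cloud_mesh(x), gs)
  recomposed <- sweep(cos_$coords %*% t(axes), 2, gs$origin, `+`)
  expect_lt(max(abs(recomposed - x)), 1e-10)
  expect_true(all(cos_$embedded))

  expect_error(control_grid(c(0, 0, 0), matrix(1, 3, 3), c(2, 2, 2)),
               "singular")
})

test_that("deformation is exact for identity, translation, and affine maps", {
  sph <- test_sphere()
  g <- fit_global_grid(sph, c(5, 5, 5), 0.05)
  co <- embed_mesh(sph, g)

  # identity: zero displacements change nothing
  expect_identical(deform_mesh(sph, co, g)$vertices, sph$vertices)

  # partition of unity: constant displacement is an exact translation
  d <- c(1.5, -2, 0.25)
  g$displacements <- matrix(rep(d, each = n_control_points(g)), ncol = 3)
  moved <- deform_mesh(sph, co, g)
  expect_lt(max(abs(sweep(moved$vertices - sph$vertices, 2, d))), 1e-9)

  # affine reproduction: lattice displaced by an affine map carries every
  # vertex to its directly-mapped position
  set.seed(31)
  for (rep_i in 1:5) {
    aff <- random_affine()
    ga <- fit_global_grid(sph, c(5, 5, 5), 0.05)
    ga$displacements <- aff$apply(ga$control_points) - ga$control_points
    got <- deform_mesh(sph, co, ga)$vertices
    expect_lt(max(abs(got - aff$apply(sph$vertices))), 1e-8)
  }

  # round trip holds on a sheared frame too
  set.seed(32)
  axes <- matrix(rnorm(9), 3, 3) + 25 * diag(3)
  gsh <- control_grid(mesh_bounds(sph)$min - 2, axes, c(4, 4, 4))
  csh <- embed_mesh(sph, gsh)
  expect_true(all(csh$embedded))
  expect_identical(deform_mesh(sph, csh, gsh)$vertices, sph$vertices)

  # coords/grid mismatch is caught
  other <- fit_global_grid(sph, c(5, 5, 5), 0.2)
  expect_error(deform_mesh(sph, co, other), "mismatch")
})

test_that("local grids leave outside vertices bitwise unchanged", {
  sph <- test_sphere()
  # lattice around the +z pole cap only
  gl <- fit_local_grid(c(0, 0, 10), c(8, 8, 6), c(5, 5, 5))
  co <- embed_mesh(sph, gl)
  expect_true(any(co$embedded) && !all(co$embedded))
  gl$displacements <- matrix(rnorm(3 * n_control_points(gl)),
                             ncol = 3)
  out <- deform_mesh(sph, co, gl)
  outside <- !co$embedded
  expect_identical(out$vertices[outside, ], sph$vertices[outside, ])
  expect_false(any(out$vertices[co$embedded, ] == sph$vertices[co$embedded, ]))
})

test_that("grid state serializes losslessly to JSON", {
  g <- fit_local_grid(c(1, 2, 3), c(4, 5, 6), c(2, 3, 4))
  set.seed(41)
  g$displacements <- matrix(rnorm(3 * n_control_points(g)), ncol = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_grid_json(g, path)
  g2 <- read_grid_json(path)
  expect_identical(g2$origin, g$origin)
  expect_identical(g2$degrees, g$degrees)
  expect_identical(g2$control_points, g$control_points)
  expect_identical(g2$displacements, g$displacements)
})
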