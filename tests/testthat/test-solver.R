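test_that("single-constraint solve matches the closed-form pseudoinverse", {
  # degree-1 lattice, constraint at the center: all weights 0.125, so
  # dP = w dX / sum(w^2) = 0.125 dX / 0.125 = dX at every control point
  g <- control_grid(c(0, 0, 0), diag(3), c(1, 1, 1))
  m <- point_cloud_mesh(rbind(c(0.5, 0.5, 0.5)))
  co <- embed_mesh(m, g)
  solved <- solve_displacements(g, co, ffd_constraint(1L, c(1, 0, 0)))
  expect_equal(solved$displacements,
               matrix(rep(c(1, 0, 0), each = 8), ncol = 3))
  moved <- deform_mesh(m, co, solved)
  expect_equal(moved$vertices[1, ], c(1.5, 0.5, 0.5))

  # zero target displacement leaves the lattice untouched
  z <- solve_displacements(g, co, ffd_constraint(1L, c(0, 0, 0)))
  expect_true(all(z$displacements == 0))

  expect_error(solve_displacements(g, co, list()), "at least one")
  outside <- embed_mesh(point_cloud_mesh(rbind(c(5, 5, 5))), g)
  expect_error(solve_displacements(g, outside, ffd_constraint(1L, c(1, 0, 0))),
               "outside")
})

test_that("multi-constraint solve agrees with the KKT minimization oracle", {
  set.seed(51)
  for (deg in list(c(1, 1, 1), c(2, 2, 2))) {
    for (k in 1:3) {
      for (trial in 1:5) {
        g <- control_grid(c(0, 0, 0), diag(3), deg)
        pts <- matrix(runif(3 * k, 0.1, 0.9), k, 3)
        m <- point_cloud_mesh(pts)
        co <- embed_mesh(m, g)
        dX <- matrix(rnorm(3 * k), k, 3)
        cons <- lapply(seq_len(k), function(i) ffd_constraint(i, dX[i, ]))
        solved <- solve_displacements(g, co, cons)
        # constraints are reproduced
        B <- bernstein_weights(deg, co$coords)
        expect_lt(max(abs(B %*% solved$displacements - dX)), 1e-8)
        # minimum-norm agreement with the independent KKT oracle
        oracle <- kkt_min_norm_oracle(B, dX)
        expect_lt(max(abs(solved$displacements - oracle)), 1e-6)
      }
    }
  }
})

test_that("solution is linear in the requested displacement", {
  set.seed(52)
  g <- control_grid(c(0, 0, 0), diag(3), c(2, 2, 2))
  m <- point_cloud_mesh(rbind(runif(3, 0.2, 0.8)))
  co <- embed_mesh(m, g)
  dX <- c(0.3, -0.7, 0.2)
  base <- solve_displacements(g, co, ffd_constraint(1L, dX))$displacements
  for (alpha in c(-2, 0.5, 3)) {
    scaled <- solve_displacements(g, co,
                                  ffd_constraint(1L, alpha * dX))$displacements
    expect_equal(scaled, alpha * base, tolerance = 1e-12)
  }
})

test_that("conflicting constraints fall back to least squares with a warning", {
  g <- control_grid(c(0, 0, 0), diag(3), c(1, 1, 1))
  p <- c(0.5, 0.5, 0.5)
  m <- point_cloud_mesh(rbind(p, p))
  co <- embed_mesh(m, g)
  cons <- list(ffd_constraint(1L, c(1, 0, 0)), ffd_constraint(2L, c(-1, 0, 0)))
  expect_warning(solved <- solve_displacements(g, co, cons), "least-squares")
  # coincident constraints average out
  expect_lt(max(abs(solved$displacements)), 1e-10)
})

test_that("a drag moves its vertex to the target and decays away from it", {
  sph <- test_sphere()
  set.seed(53)
  # single-constraint exactness across random drags
  for (trial in 1:20) {
    vid <- sample.int(nrow(sph$vertices), 1)
    dX <- rnorm(3, sd = 1)
    g <- fit_global_grid(sph, c(5, 5, 5), 0.05)
    moved <- apply_drag(sph, g, vid, dX)
    expect_lt(max(abs(moved$vertices[vid, ] - (sph$vertices[vid, ] + dX))),
              1e-8)
    # displacement field bound: |x_ffd - x| <= |dX| ||w_x|| / ||w_c||
    co <- embed_mesh(sph, g)
    W <- bernstein_weights(c(5, 5, 5), co$coords)
    wc <- W[vid, ]
    bound <- sqrt(sum(dX^2)) * sqrt(rowSums(W^2)) / sqrt(sum(wc^2))
    disp <- sqrt(rowSums((moved$vertices - sph$vertices)^2))
    expect_true(all(disp <= bound + 1e-9))
  }

  # zero drag is the identity
  g <- fit_global_grid(sph, c(5, 5, 5), 0.05)
  expect_identical(apply_drag(sph, g, 7L, c(0, 0, 0))$vertices, sph$vertices)

  # outward 2 mm drag: dragged vertex moves exactly 2 mm, the antipodal
  # vertex strictly (and substantially) less
  vid <- which.max(sph$vertices[, 3])
  anti <- which.min(sph$vertices[, 3])
  g <- fit_global_grid(sph, c(5, 5, 5), 0.05)
  moved <- apply_drag(sph, g, vid, c(0, 0, 2))
  disp <- sqrt(rowSums((moved$vertices - sph$vertices)^2))
  expect_equal(disp[vid], 2, tolerance = 1e-6)
  expect_gt(disp[anti], 0)
  expect_lt(disp[anti], disp[vid])

  # input mesh is untouched
  expect_equal(sph$vertices, test_sphere()$vertices)
})

test_that("a drag under a tight local grid leaves the rest of the mesh alone", {
  sph <- test_sphere()
  vid <- which.max(sph$vertices[, 3])
  gl <- fit_local_grid(sph$vertices[vid, ], c(6, 6, 6), c(5, 5, 5))
  co <- embed_mesh(sph, gl)
  moved <- apply_drag(sph, gl, vid, c(0, 0, 1.5))
  outside <- !co$embedded
  expect_gt(sum(outside), 0)
  expect_identical(moved$vertices[outside, ], sph$vertices[outside, ])
  expect_equal(moved$vertices[vid, ], sph$vertices[vid, ] + c(0, 0, 1.5),
               tolerance = 1e-8)
})
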