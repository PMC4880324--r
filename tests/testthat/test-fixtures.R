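test_that("fixtures are reproducible and match analytic overlap values", {
  spec <- default_sphere_fixture()
  fx <- make_fixture(spec)

  # unperturbed fixture: initial mesh is the ground truth
  spec0 <- default_sphere_fixture(scale = 1.0)
  fx0 <- make_fixture(spec0)
  expect_identical(fx0$initial_mesh$vertices, fx0$gt_mesh$vertices)
  d0 <- dice_coefficient(rasterize_mesh(fx0$initial_mesh, spec0$geometry),
                         fx0$gt_mask)
  expect_gte(d0, 0.98)

  # 10% global scale: nested-ball closed form 2 r^3 / (r^3 + (1.1 r)^3)
  analytic <- 2 / (1 + 1.1^3)
  di <- dice_coefficient(rasterize_mesh(fx$initial_mesh, spec$geometry),
                         fx$gt_mask)
  expect_lt(abs(di - analytic), 0.02)

  # same spec + seed twice: bitwise-identical fixtures
  fx2 <- make_fixture(default_sphere_fixture())
  expect_identical(fx2$initial_mesh$vertices, fx$initial_mesh$vertices)
  expect_identical(fx2$gt_mask$data, fx$gt_mask$data)

  # perturbations leave the caller's RNG untouched
  set.seed(99); before <- .Random.seed
  invisible(make_fixture(fixture_spec(
    spec$geometry, spec$center, c(16, 16, 16),
    perturbation = list(kind = "smooth_bump", magnitude = 3, seed = 5))))
  expect_identical(.Random.seed, before)

  # self-intersection guards
  expect_error(make_fixture(fixture_spec(
    spec$geometry, spec$center, c(16, 16, 16),
    perturbation = list(kind = "smooth_bump", magnitude = 10, seed = 1))),
    "self-intersect")
  expect_error(make_fixture(fixture_spec(
    spec$geometry, spec$center, c(16, 16, 16),
    perturbation = list(kind = "random_ffd", magnitude = 8, seed = 1))),
    "too large")
})

test_that("bump and lattice-jitter perturbations deform where they should", {
  spec <- default_sphere_fixture()
  bump <- make_fixture(fixture_spec(
    spec$geometry, spec$center, c(16, 16, 16),
    perturbation = list(kind = "smooth_bump", magnitude = 5, seed = 7)))
  dr <- sqrt(rowSums(sweep(bump$initial_mesh$vertices, 2, spec$center)^2)) - 16
  expect_gt(max(dr), 4.9)                      # bump apex (no vertex sits
  expect_lte(max(dr), 5 + 1e-9)                # exactly on the bump axis)
  expect_gt(mean(abs(dr) < 1e-9), 0.5)         # most of the sphere untouched

  jit <- make_fixture(fixture_spec(
    spec$geometry, spec$center, c(16, 16, 16),
    perturbation = list(kind = "random_ffd", magnitude = 1.5, seed = 3)))
  d <- sqrt(rowSums((jit$initial_mesh$vertices - jit$gt_mesh$vertices)^2))
  expect_gt(mean(d), 0.2)
  expect_lt(max(d), 8)
})

test_that("scripted user is deterministic and stops immediately on a perfect start", {
  spec0 <- default_sphere_fixture(scale = 1.0)
  fx0 <- make_fixture(spec0)
  tr0 <- scripted_user(fx0$initial_mesh, fx0$gt_mask, fx0$gt_mesh,
                       spec0$geometry)
  expect_equal(tr0$n_interactions, 0L)
  expect_equal(nrow(tr0$steps), 0L)
  expect_gte(tr0$initial_dice, 0.98)
  expect_identical(tr0$final_mesh$vertices, fx0$initial_mesh$vertices)
})

test_that("scripted user corrects the oversized sphere under the global grid", {
  fx <- make_fixture(default_sphere_fixture())
  tr <- scripted_user(fx$initial_mesh, fx$gt_mask, fx$gt_mesh,
                      fx$spec$geometry, policy = "global",
                      max_interactions = 100L)
  expect_gt(tr$final_dice, tr$initial_dice)
  expect_lte(tr$n_interactions, 100L)
  expect_equal(nrow(tr$steps), tr$n_interactions)
  expect_true(all(tr$steps$dice >= 0 & tr$steps$dice <= 1))

  # reproducibility, interaction for interaction
  tr2 <- scripted_user(fx$initial_mesh, fx$gt_mask, fx$gt_mesh,
                       fx$spec$geometry, policy = "global",
                       max_interactions = 100L)
  expect_identical(tr2$steps$dice, tr$steps$dice)
  expect_identical(tr2$final_mesh$vertices, tr$final_mesh$vertices)
})

test_that("local policy confines the correction; the global grid does not", {
  spec <- default_sphere_fixture()
  fx <- make_fixture(fixture_spec(
    spec$geometry, spec$center, c(16, 16, 16),
    perturbation = list(kind = "smooth_bump", magnitude = 5, seed = 7)))
  # far hemisphere relative to the (seeded) bump direction
  set.seed(7)
  dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
  far <- as.numeric(sweep(fx$initial_mesh$vertices, 2, spec$center) %*% dirv) < 0

  trl <- scripted_user(fx$initial_mesh, fx$gt_mask, fx$gt_mesh, spec$geometry,
                       policy = "local", dice_target = 0.99,
                       max_interactions = 10L)
  expect_gt(trl$n_interactions, 0L)
  expect_gt(trl$final_dice, trl$initial_dice)
  moved_l <- rowSums(trl$final_mesh$vertices != fx$initial_mesh$vertices) > 0
  expect_equal(sum(moved_l & far), 0L)

  trg <- scripted_user(fx$initial_mesh, fx$gt_mask, fx$gt_mesh, spec$geometry,
                       policy = "global", dice_target = 0.99,
                       max_interactions = 3L)
  moved_g <- rowSums(trg$final_mesh$vertices != fx$initial_mesh$vertices) > 0
  expect_gt(sum(moved_g & far), 0L)
})
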