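# Shared fixtures and independent oracles for the test suite.

# Independent scalar Bernstein evaluation (direct binomial expansion),
# deliberately separate from the package's tensor-product code path.
bernstein_1d_oracle <- function(d, i, x) {
  choose(d, i) * (1 - x)^(d - i) * x^i
}

# Equality-constrained quadratic minimization oracle for the inverse-FFD
# solve: minimize ||p||^2 subject to B p = d, via the full KKT linear system
# [2I B'; B 0] [p; lambda] = [0; d], solved per spatial component with base
# solve(). Independent of the pseudoinverse route used by the package.
kkt_min_norm_oracle <- function(B, dX) {
  nc <- ncol(B); k <- nrow(B)
  K <- rbind(cbind(2 * diag(nc), t(B)),
             cbind(B, matrix(0, k, k)))
  out <- matrix(0, nc, ncol(dX))
  for (j in seq_len(ncol(dX))) {
    sol <- solve(K, c(rep(0, nc), dX[, j]))
    out[, j] <- sol[seq_len(nc)]
  }
  out
}

# Random affine map and its direct application (oracle for affine
# reproduction of the FFD).
random_affine <- function() {
  A <- matrix(stats::rnorm(9, sd = 0.3), 3, 3) + diag(3)
  b <- stats::rnorm(3)
  list(apply = function(x) sweep(x %*% t(A), 2, b, `+`), A = A, b = b)
}

# A vertex cloud posing as a mesh (no faces); valid input for embedding and
# deformation, used where connectivity is irrelevant.
point_cloud_mesh <- function(v) triangle_mesh(v, matrix(0L, 0L, 3L))

# Small axis-aligned cube mesh [0,1]^3 (12 triangles, watertight, outward).
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  triangle_mesh(v, f)
}

# Default small sphere-phantom pieces shared by several files.
test_geometry <- function() image_geometry(c(32L, 32L, 32L), c(1, 1, 1),
                                           c(-15.5, -15.5, -15.5))
test_sphere <- function(r = 10, subdiv = 3L) ellipsoid_mesh(c(0, 0, 0),
                                                            rep(r, 3), subdiv)
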