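test_that("element mass matrix matches the closed form (A/12)(1 + I)", {
  m <- unit_right_mesh()
  M <- as.matrix(assemble_mass(m))
  A <- 0.5
  expect_equal(M, A / 12 * matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("mass matrix row sums total the domain area (partition of unity)", {
  m <- small_ellipse()
  M <- assemble_mass(m)
  expect_equal(sum(M), mesh_area(m), tolerance = 1e-12)
  expect_equal(as.matrix(M), t(as.matrix(M)), tolerance = 1e-15)
  ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("assembled matrices agree with the quadrature oracle to 1e-12", {
  m <- small_ellipse()
  expect_lt(max(abs(as.matrix(assemble_mass(m)) -
                    oracle_assemble(m, "mass"))), 1e-12)
  expect_lt(max(abs(as.matrix(assemble_stiffness(m, 1.7)) -
                    oracle_assemble(m, "stiffness", coeff = 1.7))), 1e-12)
  set.seed(11)
  phi <- runif(nrow(m$nodes), -1, 1)
  expect_lt(max(abs(as.matrix(assemble_drift(m, phi, 0.3)) -
                    oracle_assemble(m, "drift", phi = phi, coeff = 0.3))),
            1e-12)
})

test_that("element stiffness matches the hand-computed unit right triangle", {
  m <- unit_right_mesh()
  K <- as.matrix(assemble_stiffness(m, 1))
  expect_equal(K, 0.5 * matrix(c(2, -1, -1, -1, 1, 0, -1, 0, 1), 3),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("stiffness rows sum to zero and u = x gives u'Ku = area", {
  m <- ellipse_mesh(1, 1, 0.3)
  K <- assemble_stiffness(m, 1)
  expect_lt(max(abs(Matrix::rowSums(K))), 1e-12)
  u <- m$nodes[, 1]  # grad u = (1, 0), so integral |grad u|^2 = area
  expect_equal(as.numeric(u %*% (K %*% u)), mesh_area(m), tolerance = 1e-12)
  ev <- eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("drift operator vanishes on constant potentials, is linear in phi", {
  m <- small_ellipse()
  n <- nrow(m$nodes)
  expect_equal(max(abs(assemble_drift(m, rep(3.7, n), 1))), 0)
  set.seed(5)
  phi <- runif(n)
  A1 <- assemble_drift(m, phi, 1)
  A2 <- assemble_drift(m, 2 * phi, 1)
  expect_lt(max(abs(A2 - 2 * A1)), 1e-13)
  # discrete mass conservation: zero column sums
  expect_lt(max(abs(Matrix::colSums(A1))), 1e-12)
})

test_that("drift entries on one triangle match exact hand integration", {
  m <- unit_right_mesh()
  phi <- c(0, 2, 3)          # grad phi = (2, 3) on the element
  dc <- 0.4
  A <- as.matrix(assemble_drift(m, phi, dc))
  grads <- list(c(-1, -1), c(1, 0), c(0, 1))
  area <- 0.5
  for (i in 1:3) for (j in 1:3) {
    expect_equal(A[i, j], dc * sum(c(2, 3) * grads[[i]]) * area / 3,
                 tolerance = 1e-14)
  }
})

test_that("Gaussian point-source load integrates to pi/sharpness", {
  m <- ellipse_mesh(2, 1, 0.2)
  b <- assemble_point_source(m, sharpness = 1000)
  expect_equal(sum(b), pi / 1000, tolerance = 0.01)
  b2 <- assemble_point_source(m, sharpness = 2000)
  expect_equal(sum(b2) / sum(b), 0.5, tolerance = 0.01)
  # decay: nodes at distance >= 1 from the centre receive nothing
  far <- sqrt(rowSums(m$nodes^2)) >= 1
  expect_lt(max(abs(b[far])), 1e-200)
  # peak load at the node nearest the centre
  expect_equal(which.max(b), which.min(rowSums(m$nodes^2)))
})

test_that("point source warns when the centre is outside the mesh", {
  m <- unit_right_mesh()
  expect_warning(assemble_point_source(m, center = c(10, 10)), "outside")
})

test_that("Dirichlet elimination enforces the boundary value exactly", {
  m <- ellipse_mesh(1, 1, 0.3)
  K <- assemble_stiffness(m, 1)
  n <- nrow(m$nodes)
  # zero source, phi = 0 boundary: solution identically zero
  s0 <- apply_dirichlet(K, numeric(n), m$boundary_nodes, 0)
  expect_lt(max(abs(Matrix::solve(s0$op, s0$rhs))), 1e-12)
  # inhomogeneous value reproduced to machine precision
  s1 <- apply_dirichlet(K, numeric(n), m$boundary_nodes, 2.5)
  u <- as.vector(Matrix::solve(s1$op, s1$rhs))
  expect_equal(u[m$boundary_nodes], rep(2.5, length(m$boundary_nodes)),
               tolerance = 1e-12)
})

test_that("Poisson problem on the unit disc recovers u(0,0) = 1/4", {
  # -Lap u = 1, u = 0 on the boundary -> u = (1 - r^2)/4
  errs <- vapply(c(0.3, 0.15, 0.075), function(h) {
    m <- ellipse_mesh(1, 1, h)
    K <- assemble_stiffness(m, 1)
    M <- assemble_mass(m)
    rhs <- as.vector(M %*% rep(1, nrow(m$nodes)))
    s <- apply_dirichlet(K, rhs, m$boundary_nodes, 0)
    u <- as.vector(Matrix::solve(s$op, s$rhs))
    ctr <- which.min(rowSums(m$nodes^2))
    abs(u[ctr] - 0.25)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.004)
})
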