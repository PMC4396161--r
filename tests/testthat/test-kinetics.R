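test_that("mass-action rates match hand evaluation at the standard state", {
  p <- suicide_params()      # k1=2, k_1=4, k2=12, k3=10, k4=2
  expect_equal(unname(reaction_rates(rep(0, 6), p)), rep(0, 6))
  # e = s = 0.5, everything else 0: only the binding flux k1*e*s = 0.5 runs
  r <- reaction_rates(c(0.5, 0.5, 0, 0, 0, 0), p)
  expect_equal(unname(r), c(-0.5, -0.5, 0.5, 0, 0, 0))
  expect_error(reaction_rates(c(-0.1, 0.5, 0, 0, 0, 0), p), "negative")
  expect_error(suicide_params(k1 = -2), "positive")
})

test_that("both conserved moieties are algebraic identities of the rates", {
  p <- suicide_params()
  set.seed(3)
  for (k in 1:25) {
    st <- runif(6, 0, 2)
    r <- reaction_rates(st, p)
    # enzyme moiety e + x + y + ei
    expect_equal(unname(r[1] + r[3] + r[4] + r[6]), 0, tolerance = 1e-14)
    # substrate moiety s + x + y + p + ei (Ei holds the bound inhibitor)
    expect_equal(unname(r[2] + r[3] + r[4] + r[5] + r[6]), 0,
                 tolerance = 1e-14)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  p <- suicide_params(k1 = 1.3, k_1 = 0.7, k2 = 2.1, k3 = 5, k4 = 0.9)
  set.seed(8)
  for (k in 1:5) {
    st <- runif(6, 0.05, 2)
    J <- reaction_jacobian(st, p)
    h <- 1e-6
    Jfd <- matrix(0, 6, 6)
    for (j in 1:6) {
      up <- st; up[j] <- up[j] + h
      dn <- st; dn[j] <- dn[j] - h
      Jfd[, j] <- (reaction_rates(up, p) - reaction_rates(dn, p)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
  J0 <- reaction_jacobian(rep(0, 6), p)
  expect_equal(J0["X", "X"], -(p$k_1 + p$k2))
  # differentiated enzyme-moiety identity: those rows sum to zero columnwise
  expect_lt(max(abs(colSums(J0[c("E", "X", "Y", "Ei"), ]))), 1e-14)
})

test_that("partition ratio and outcome classification follow (1+r)*mu", {
  expect_equal(partition_ratio(suicide_params(k3 = 10, k4 = 2)), 5)
  expect_equal(partition_ratio(suicide_params(k3 = 3, k4 = 3)), 1)
  expect_equal(partition_ratio(suicide_params(k3 = 6, k4 = 2)),
               2 * partition_ratio(suicide_params(k3 = 3, k4 = 2)))
  out <- classify_outcome(5, 0.5, 0.5)
  expect_equal(out$tatsunami, 6)
  expect_equal(out$waley, 5)
  expect_identical(out$outcome, "substrate_exhausted")
  expect_identical(classify_outcome(1, 0.5, 1)$outcome, "boundary")
  expect_identical(classify_outcome(0, 0.5, 1)$outcome, "enzyme_inactivated")
  expect_error(classify_outcome(5, 0.5, 0), "s0")
})

test_that("well-mixed RK4 trajectory conserves moieties and matches deSolve", {
  p <- suicide_params()
  run <- simulate_well_mixed(p, T = 2, dt = 1e-3)
  tr <- run$trajectory
  enz <- tr$E + tr$X + tr$Y + tr$Ei
  sub <- tr$S + tr$X + tr$Y + tr$P + tr$Ei
  expect_lt(max(abs(enz - enz[1])), 1e-10)
  expect_lt(max(abs(sub - sub[1])), 1e-10)
  expect_gte(min(as.matrix(tr[, -1])), -1e-9)
  skip_if_not_installed("deSolve")
  ode_fn <- function(t, y, parms) list(unname(reaction_rates(pmax(y, 0), p)))
  ref <- deSolve::ode(c(0.5, 0.5, 0, 0, 0, 0), c(0, 2), ode_fn, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(run$final), unname(ref[2, 2:7]), tolerance = 1e-7)
})

test_that("endpoint error shrinks like dt^4 under step halving", {
  p <- suicide_params()
  ref <- simulate_well_mixed(p, T = 1, dt = 1e-4)$final
  e1 <- max(abs(simulate_well_mixed(p, T = 1, dt = 8e-3)$final - ref))
  e2 <- max(abs(simulate_well_mixed(p, T = 1, dt = 4e-3)$final - ref))
  expect_equal(log2(e1 / e2), 4, tolerance = 0.5)
})

test_that("long-time behaviour matches the Tatsunami prediction", {
  # (1+r)mu = 6 > 1: substrate exhausted while free enzyme survives
  p <- suicide_params()
  run <- simulate_well_mixed(p, c(0.5, 0.5, 0, 0, 0, 0), T = 25, dt = 1e-3)
  expect_identical(run$outcome, "substrate_exhausted")
  expect_lt(run$final[["S"]], 1e-3 * 0.5)
  expect_gt(run$final[["E"]] + run$final[["Ei"]], 0)
  expect_lt(run$final[["Ei"]], 0.5)
  expect_lt(run$error_estimate, 1e-10)
})

test_that("classification agrees with simulation across the (1+r)mu = 1 line", {
  # sweep the partition ratio with mu = 1/4 fixed: boundary at r = 3
  for (r in c(1, 2, 5, 8)) {
    p <- suicide_params(k3 = r, k4 = 1)
    pred <- classify_outcome(p, e0 = 0.25, s0 = 1)$outcome
    run <- simulate_well_mixed(p, c(0.25, 1, 0, 0, 0, 0),
                               T = 100, dt = 2e-3)
    expect_identical(run$outcome, pred,
                     label = sprintf("r = %g simulated outcome", r))
  }
})
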