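test_that("scalar decay reproduces the closed-form exponential", {
  net <- decay_network()
  traj <- simulate_network(net, setup = unit_setup())
  expect_equal(unname(traj$states[nrow(traj$states), 1]), exp(-1),
               tolerance = 1e-8)
  # interpolant reproduces stored states at grid points
  probe <- trajectory_states(traj, traj$times[c(1, 25, 50, 100)])
  expect_equal(unname(probe[, 1]), unname(traj$states[c(1, 25, 50, 100), 1]),
               tolerance = 1e-12)
  expect_identical(traj$times[1], 0)
  expect_identical(traj$times[length(traj$times)], 1)
})

test_that("sensor stoichiometry times flux reproduces the rate equations", {
  net <- sensor_network(x5_total = 10)
  # independent hand-coded right-hand side
  rhs_oracle <- function(x, k, y) {
    c(k[1] * (10 - x[5]) + k[2] * x[5] - k[3] * x[1],
      k[4] * x[1] - 2 * k[5] * x[2]^2 + 2 * k[6] * x[3] - k[11] * x[2],
      k[5] * x[2]^2 - k[6] * x[3] - k[7] * x[3] * y + k[8] * x[4] -
        k[9] * (10 - x[5]) * x[3] + k[10] * x[5] - k[11] * x[3],
      k[7] * x[3] * y - k[8] * x[4] - k[11] * x[4],
      k[9] * (10 - x[5]) * x[3] - k[10] * x[5] - k[11] * x[5])
  }
  set.seed(42)
  for (rep in 1:20) {
    x <- stats::runif(5, 0, 50); x[5] <- stats::runif(1, 0, 10)
    k <- stats::runif(11, 0, 2)
    y <- stats::runif(1, 0, 100)
    expect_equal(as.numeric(net$stoich %*% net$flux(x, k, y, 0)),
                 rhs_oracle(x, k, y), tolerance = 1e-12)
  }
})

test_that("sensor derivatives at the zero state match direct arithmetic", {
  net <- sensor_network(x5_total = 10)
  dx <- as.numeric(net$stoich %*% net$flux(rep(0, 5), net$params, 0, 0))
  # only basal transcription fires: k1 * x5_total = 0.02 * 10
  expect_equal(dx, c(0.2, 0, 0, 0, 0), tolerance = 1e-14)
  expect_equal(unname(net$params["k1"]), 0.02)
  expect_equal(unname(net$params["k7"]), 0.011)
  expect_identical(net$n, 5L)
  expect_identical(net$p, 11L)
})

test_that("analytic flux Jacobians agree with central finite differences", {
  net <- sensor_network()
  set.seed(7)
  for (rep in 1:100) {
    x <- stats::runif(5, 0.1, 30); x[5] <- stats::runif(1, 0, 10)
    k <- stats::runif(11, 0.01, 2)
    y <- stats::runif(1, 0, 100)
    Jx <- net$flux_jac_x(x, k, y, 0)
    Jx_fd <- fd_jacobian(function(xx) net$flux(xx, k, y, 0), x)
    expect_lt(max(abs(Jx - Jx_fd)) / max(abs(Jx_fd)), 1e-6)
    Jk <- net$flux_jac_k(x, k, y, 0)
    Jk_fd <- fd_jacobian(function(kk) net$flux(x, kk, y, 0), k)
    expect_lt(max(abs(Jk - Jk_fd)) / max(abs(Jk_fd)), 1e-6)
  }
})

test_that("steady states are found, refined and invariant", {
  # fixed point of dx/dt = k(1-x)
  xs <- steady_state(growth_network())
  expect_equal(unname(xs), 1, tolerance = 1e-9)

  net <- sensor_network()
  xs <- steady_state(net)
  resid <- net$stoich %*% net$flux(xs, net$params, 0, 0)
  expect_lt(max(abs(resid)), 1e-9)
  expect_true(all(xs >= 0))
  # invariance: simulating from x* stays at x*
  traj <- simulate_network(net, setup = simulation_setup(xs, 500))
  expect_equal(unname(traj$states[nrow(traj$states), ]), unname(xs),
               tolerance = 1e-6)
})

test_that("promoter conservation and nonnegativity hold along the pulse", {
  net <- sensor_network(x5_total = 10)
  setup <- simulation_setup(steady_state(net), 600)
  traj <- simulate_network(net, setup = setup,
                           input = input_signal(c(0, 100, 300), c(0, 100, 0)))
  expect_true(all(traj$states >= -setup$atol))
  expect_true(all(traj$states[, "x5"] <= 10 + setup$atol))
  # the inhibited complex appears only once the inhibitor is present
  x4 <- traj$states[, "x4"]
  expect_lt(max(x4[traj$times <= 100]), 1e-6)
  expect_gt(max(x4[traj$times > 100 & traj$times < 300]), 1)
})

test_that("input signals clamp to boundary levels and validate", {
  pulse <- input_signal(c(0, 100, 300), c(0, 100, 0))
  expect_equal(input_level(pulse, c(-5, 0, 50, 100, 299.9, 300, 1e4)),
               c(0, 0, 0, 100, 100, 0, 0))
  expect_error(input_signal(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(input_signal(0, -1), "nonnegative")
  net <- decay_network()
  expect_error(simulate_network(net, k = -1, setup = unit_setup()),
               "nonnegative")
  expect_error(simulate_network(net, k = c(1, 2), setup = unit_setup()),
               "length")
})

test_that("integration failure carries the last reached time", {
  # finite-time blow-up: dx/dt = k x^2, x(0) = 2, escapes at t = 1/(k x0)
  net <- reaction_network(
    species = "x", stoich = matrix(1, 1, 1),
    flux = function(x, k, u, t) k[1] * x[1]^2,
    flux_jac_x = function(x, k, u, t) matrix(2 * k[1] * x[1], 1, 1),
    flux_jac_k = function(x, k, u, t) matrix(x[1]^2, 1, 1),
    param_names = "k", params = c(k = 1))
  err <- tryCatch(
    simulate_network(net, setup = simulation_setup(2, 5)),
    specmap_integration_failure = function(e) e)
  expect_s3_class(err, "specmap_integration_failure")
  expect_lt(err$t_last, 5)
})

test_that("mass-action builder assembles fluxes and exact Jacobians", {
  net <- mass_action_network(
    species = c("A", "B"),
    params = c(kf = 0.3, kr = 0.1, kin = 0.05),
    reactions = list(
      list(rate = "kf", reactants = c(A = 2), products = c(B = 1)),
      list(rate = "kr", reactants = c(B = 1), products = c(A = 2)),
      list(rate = "kin", reactants = c(B = 1), products = NULL,
           input_exponent = 1)))
  expect_identical(dim(net$stoich), c(2L, 3L))
  x <- c(3, 4); u <- 2
  expect_equal(as.numeric(net$flux(x, net$params, u, 0)),
               c(0.3 * 9, 0.1 * 4, 0.05 * 4 * 2), tolerance = 1e-14)
  set.seed(11)
  for (rep in 1:20) {
    x <- stats::runif(2, 0, 5); u <- stats::runif(1, 0, 3)
    Jx_fd <- fd_jacobian(function(xx) net$flux(xx, net$params, u, 0), x)
    expect_equal(net$flux_jac_x(x, net$params, u, 0), Jx_fd,
                 tolerance = 1e-6)
  }
  expect_error(mass_action_network(
    species = "A", params = c(k = 1),
    reactions = list(list(rate = "k", reactants = c(Z = 1),
                          products = NULL))),
    "unknown species")
})
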