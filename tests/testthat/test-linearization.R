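test_that("decay sensitivity matches the closed form -t x0 e^{-kt}", {
  net <- decay_network()
  vs <- solve_variational(net, setup = unit_setup(n_grid = 50),
                          subset = design_subset(net, "k"))
  s <- vs$sensitivities[, 1, 1]
  expect_equal(s[1], 0)                       # zero initial condition
  expect_equal(unname(s), -vs$times * exp(-vs$times), tolerance = 1e-8)
  expect_equal(unname(s[length(s)]), -exp(-1), tolerance = 1e-8)
})

test_that("sensor state sensitivities match finite differences", {
  # probe while the perturbed rates are actively shaping the response
  # (during the pulse and shortly after washout); by the end of the horizon
  # the transient has relaxed and both sides of the comparison vanish
  o <- cs_objects()
  vs <- solve_variational(o$net, setup = o$setup, input = o$inp,
                          subset = o$subset)
  probes <- c(150, 250, 320)
  n <- o$net$n
  hi <- simulation_setup(o$setup$x0, o$setup$horizon,
                         rtol = 1e-10, atol = 1e-12, n_grid = o$setup$n_grid)
  for (j in 1:2) {
    h <- 1e-5 * o$net$params[o$subset$idx[j]]
    kp <- o$net$params; kp[o$subset$idx[j]] <- kp[o$subset$idx[j]] + h
    km <- o$net$params; km[o$subset$idx[j]] <- km[o$subset$idx[j]] - h
    xp <- simulate_network(o$net, kp, hi, o$inp)
    xm <- simulate_network(o$net, km, hi, o$inp)
    for (tp in probes) {
      fd <- (trajectory_states(xp, tp) - trajectory_states(xm, tp)) / (2 * h)
      St <- trajectory_states(vs$full, tp)[1, n + (j - 1) * n + seq_len(n)]
      expect_lt(sqrt(sum((St - fd)^2)) / sqrt(sum(fd^2)), 1e-4)
    }
  }
})

test_that("linearize recovers the closed-form derivative of F", {
  net <- decay_network()
  sub <- design_subset(net, "k")
  # zero kernel: L is exactly the zero matrix
  zero <- convolution_kernel(function(s) rep(0, length(s)), 1, 1)
  lin0 <- linearize(net, zero, setup = unit_setup(), subset = sub)
  expect_true(all(lin0$L == 0))
  # F(k) = (1 - e^{-k})/k, dF/dk at 1 = 2/e - 1
  lin <- linearize(net, integral_kernel(1, 1), setup = unit_setup(),
                   subset = sub)
  expect_equal(as.numeric(lin$L), 2 * exp(-1) - 1, tolerance = 1e-6)
  expect_equal(lin$f0, 1 - exp(-1), tolerance = 1e-8)
})

test_that("forward map composes simulate and features consistently", {
  net <- decay_network()
  sub <- design_subset(net, "k")
  f <- forward_map(net, integral_kernel(1, 1), 1, unit_setup(n_grid = 200),
                   subset = sub)
  expect_equal(f, 1 - exp(-1), tolerance = 1e-8)
  expect_error(forward_map(net, integral_kernel(1, 1), -0.5, unit_setup(),
                           subset = sub), "nonnegative")
  # self-consistency with the f0 stored by linearize, on the sensor
  o <- cs_objects()
  lin <- cs_linmap()
  f0 <- forward_map(o$net, o$kernel, lin$k0_design, o$setup, o$inp, o$subset)
  expect_equal(f0, lin$f0, tolerance = 1e-8)
})

test_that("sensor linearization satisfies the first-order expansion", {
  o <- cs_objects()
  lin <- cs_linmap()
  set.seed(3)
  u <- stats::rnorm(2); u <- u / sqrt(sum(u^2))
  ratios <- sapply(0:4, function(i) {
    dk <- 0.04 / 2^i * u * lin$k0_design
    f <- forward_map(o$net, o$kernel, lin$k0_design + dk, o$setup, o$inp,
                     o$subset)
    sqrt(sum((f - lin$f0 - as.numeric(lin$L %*% dk))^2)) / sqrt(sum(dk^2))
  })
  # remainder over ||dk|| must shrink as dk is halved
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[5], ratios[1] / 8)
})

test_that("augmented-ODE L agrees with quadrature of the sensitivities", {
  o <- cs_objects()
  lin <- cs_linmap()
  vs <- solve_variational(o$net, setup = o$setup, input = o$inp,
                          subset = o$subset)
  full <- vs$full
  n <- o$net$n
  # integral form: L = int (dg/dx)(s, x(s)) (dx/dk)(s) ds over the support
  L_quad <- matrix(0, 2, 2)
  for (i in 1:2) {
    dom <- o$kernel$support[[i]]
    integrand <- function(tt) {
      vapply(tt, function(t1) {
        y <- trajectory_states(full, t1)
        x <- y[1, seq_len(n)]
        S <- matrix(y[1, n + seq_len(n * 2)], n, 2)
        (o$kernel$g_jac_x(t1, x) %*% S)[i, j]
      }, numeric(1))
    }
    for (j in 1:2)
      for (r in seq_len(nrow(dom)))
        L_quad[i, j] <- L_quad[i, j] +
          stats::integrate(integrand, dom[r, 1], dom[r, 2],
                           rel.tol = 1e-10)$value
  }
  expect_equal(unname(L_quad), unname(lin$L), tolerance = 1e-6)
})

test_that("linear chain matches the matrix-exponential solution", {
  net <- chain_network()
  setup <- simulation_setup(c(1, 0), 2, n_grid = 50)
  traj <- simulate_network(net, setup = setup)
  A <- matrix(c(-1, 0, 1, -0.5), 2, 2, byrow = TRUE)
  for (t in c(0.5, 1, 2)) {
    exact <- as.numeric(Matrix::expm(A * t) %*% c(1, 0))
    expect_equal(unname(trajectory_states(traj, t)[1, ]), exact,
                 tolerance = 1e-7)
  }
  # variational sensitivities against finite differences
  vs <- solve_variational(net, setup = setup,
                          subset = design_subset(net, c("k1", "k2")))
  nt <- dim(vs$sensitivities)[1]
  for (j in 1:2) {
    h <- 1e-6
    kp <- net$params; kp[j] <- kp[j] + h
    km <- net$params; km[j] <- km[j] - h
    xp <- simulate_network(net, kp, setup)
    xm <- simulate_network(net, km, setup)
    fd <- (xp$states[nrow(xp$states), ] - xm$states[nrow(xm$states), ]) /
      (2 * h)
    expect_equal(unname(vs$sensitivities[nt, , j]), unname(fd),
                 tolerance = 1e-6)
  }
})
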