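options(specmap.log_level = "ERROR")

# ---- toy networks with closed-form behavior --------------------------------

# dx/dt = -k x, x(0) = 1: x(t) = e^{-kt}, dx/dk = -t e^{-kt},
# F(k) = int_0^1 x dt = (1 - e^{-k})/k
decay_network <- function() {
  reaction_network(
    species = "x", stoich = matrix(-1, 1, 1),
    flux = function(x, k, u, t) k[1] * x[1],
    flux_jac_x = function(x, k, u, t) matrix(k[1], 1, 1),
    flux_jac_k = function(x, k, u, t) matrix(x[1], 1, 1),
    param_names = "k", params = c(k = 1))
}

# dx/dt = k (1 - x): fixed point x* = 1
growth_network <- function() {
  reaction_network(
    species = "x", stoich = matrix(1, 1, 1),
    flux = function(x, k, u, t) k[1] * (1 - x[1]),
    flux_jac_x = function(x, k, u, t) matrix(-k[1], 1, 1),
    flux_jac_k = function(x, k, u, t) matrix(1 - x[1], 1, 1),
    param_names = "k", params = c(k = 1))
}

# dx_i/dt = k_i, x(0) = 0: with h == 1 features, F(k) = k * T^2 / 2 --
# an exactly linear forward map with full-row-rank L = (T^2/2) I
linear_source_network <- function() {
  reaction_network(
    species = c("x1", "x2"), stoich = diag(2),
    flux = function(x, k, u, t) c(k[1], k[2]),
    flux_jac_x = function(x, k, u, t) matrix(0, 2, 2),
    flux_jac_k = function(x, k, u, t) diag(2),
    param_names = c("k1", "k2"), params = c(k1 = 1, k2 = 1))
}

# dx/dt = k^2, x(0) = 0: with the h == 1 feature, F(k) = k^2/2, so the
# secant slope at k0 = 1 over a step D is 1 + D/2 and the rank-one
# correction norm is exactly |D|/2
quadratic_network <- function() {
  reaction_network(
    species = "x", stoich = matrix(1, 1, 1),
    flux = function(x, k, u, t) k[1]^2,
    flux_jac_x = function(x, k, u, t) matrix(0, 1, 1),
    flux_jac_k = function(x, k, u, t) matrix(2 * k[1], 1, 1),
    param_names = "k", params = c(k = 1))
}

# two-species chain dx1 = -k1 x1, dx2 = k1 x1 - k2 x2 (linear system)
chain_network <- function() {
  reaction_network(
    species = c("x1", "x2"),
    stoich = matrix(c(-1, 1, 0, -1), 2, 2),
    flux = function(x, k, u, t) c(k[1] * x[1], k[2] * x[2]),
    flux_jac_x = function(x, k, u, t)
      matrix(c(k[1], 0, 0, k[2]), 2, 2, byrow = TRUE),
    flux_jac_k = function(x, k, u, t)
      matrix(c(x[1], 0, 0, x[2]), 2, 2, byrow = TRUE),
    param_names = c("k1", "k2"), params = c(k1 = 1, k2 = 0.5))
}

unit_setup <- function(x0 = 1, horizon = 1, n_grid = 100)
  simulation_setup(x0, horizon, n_grid = n_grid)

# h == 1 convolution features (per-species time integrals)
integral_kernel <- function(horizon, n)
  convolution_kernel(function(s) rep(1, length(s)), horizon, n)

# ---- finite-difference oracles ---------------------------------------------

fd_jacobian <- function(f, x, h = NULL) {
  fx <- f(x)
  J <- matrix(0, length(fx), length(x))
  for (i in seq_along(x)) {
    hi <- if (is.null(h)) max(1e-6 * abs(x[i]), 1e-9) else h
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    J[, i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  J
}

# ---- shared case-study objects (built once per test run) -------------------

.cs_cache <- new.env(parent = emptyenv())

cs_objects <- function() {
  if (is.null(.cs_cache$obj)) {
    cfg <- sensor_case_study()
    net <- specmap:::config_network(cfg)
    inp <- specmap:::config_input(cfg)
    setup <- specmap:::config_setup(cfg, net)
    kernel <- specmap:::config_kernel(cfg, net)
    subset <- design_subset(net, unlist(cfg$algorithm$design_parameters))
    region <- specmap:::config_region(cfg)
    .cs_cache$obj <- list(cfg = cfg, net = net, inp = inp, setup = setup,
                          kernel = kernel, subset = subset, region = region,
                          eps = cfg$algorithm$eps)
  }
  .cs_cache$obj
}

cs_linmap <- function() {
  if (is.null(.cs_cache$linmap)) {
    o <- cs_objects()
    .cs_cache$linmap <- linearize(o$net, o$kernel, setup = o$setup,
                                  input = o$inp, subset = o$subset)
  }
  .cs_cache$linmap
}

# the full covering experiment of the shipped case study (shared by the
# coverage-related acceptance checks)
cs_cover <- function() {
  if (is.null(.cs_cache$cover)) {
    o <- cs_objects()
    .cs_cache$cover <- cover_region(
      o$region, o$net, o$kernel, eps = o$eps,
      max_balls = o$cfg$algorithm$max_balls,
      seed = specmap:::stage_seeds(o$cfg$algorithm$seed)$cover,
      setup = o$setup, input = o$inp, subset = o$subset,
      rho_config = o$cfg$algorithm$rho,
      coverage_target = o$cfg$algorithm$coverage_target,
      n_mc = o$cfg$algorithm$n_mc)
  }
  .cs_cache$cover
}
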