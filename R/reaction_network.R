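#' Mass-action reaction network
#'
#' Container for a reaction-rate-equation model
#' \deqn{\frac{dx}{dt} = N\,v(x, k, u(t)),}
#' where `N` is the integer stoichiometric matrix (species in rows, reactions
#' in columns), `v` the nonnegative reaction flux vector, `k` the kinetic
#' parameter vector and `u(t)` a scalar, piecewise-constant external input
#' (see [input_signal()]). Concentrations are in nM, time in seconds.
#'
#' Analytic flux Jacobians with respect to state and parameters are required;
#' they drive the variational (forward-sensitivity) integration in
#' [linearize()] and the Newton refinement in [steady_state()].
#'
#' @param species character vector of species names (length `n`).
#' @param stoich `n x q` integer matrix `N`.
#' @param flux `function(x, k, u, t)` returning `q` nonnegative fluxes.
#' @param flux_jac_x `function(x, k, u, t)` returning the `q x n` matrix
#'   of partial derivatives of the flux with respect to the state.
#' @param flux_jac_k `function(x, k, u, t)` returning the `q x p` matrix
#'   of partial derivatives with respect to the parameters.
#' @param param_names character vector of parameter names (length `p`).
#' @param params optional named vector of nominal parameter values; used as
#'   the default `k` by downstream functions.
#' @param conserved_bounds optional named list of `c(lo, hi)` per-species
#'   box constraints implied by conservation relations (documentation and
#'   simulation checks only).
#' @return An object of class `reaction_network`.
#' @seealso [sensor_network()], [mass_action_network()], [simulate_network()]
#' @export
reaction_network <- function(species, stoich, flux, flux_jac_x, flux_jac_k,
                             param_names, params = NULL,
                             conserved_bounds = NULL) {
  n <- length(species)
  p <- length(param_names)
  stoich <- as.matrix(stoich)
  cc <- check_collector()
  cc$add(n >= 1L, "at least one species required")
  cc$add(nrow(stoich) == n,
         sprintf("stoichiometry has %d rows, expected %d (one per species)",
                 nrow(stoich), n))
  cc$add(all(stoich == round(stoich)), "stoichiometry must be integer-valued")
  cc$add(is.function(flux), "flux must be a function(x, k, u, t)")
  cc$add(is.function(flux_jac_x), "flux_jac_x must be a function")
  cc$add(is.function(flux_jac_k), "flux_jac_k must be a function")
  cc$add(p >= 1L, "at least one parameter required")
  if (!is.null(params)) {
    cc$add(length(params) == p, "params length must match param_names")
    cc$add(all(params >= 0), "nominal parameters must be nonnegative")
    params <- stats::setNames(as.numeric(params), param_names)
  }
  cc$fail_if_any("invalid reaction network")

  q <- ncol(stoich)
  net <- structure(
    list(species = species, stoich = stoich, flux = flux,
         flux_jac_x = flux_jac_x, flux_jac_k = flux_jac_k,
         param_names = param_names, params = params,
         conserved_bounds = conserved_bounds,
         n = n, q = q, p = p),
    class = "reaction_network")

  # probe once so dimension errors surface at construction time
  x <- rep(1, n); k <- if (is.null(params)) rep(1, p) else params
  vv <- flux(x, k, 0, 0)
  jx <- flux_jac_x(x, k, 0, 0)
  jk <- flux_jac_k(x, k, 0, 0)
  cc <- check_collector()
  cc$add(length(vv) == q, sprintf("flux returns %d values, expected q = %d",
                                  length(vv), q))
  cc$add(all(dim(jx) == c(q, n)), "flux_jac_x must return a q x n matrix")
  cc$add(all(dim(jk) == c(q, p)), "flux_jac_k must return a q x p matrix")
  cc$fail_if_any("invalid reaction network")
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions, %d parameters\n",
              x$n, x$q, x$p))
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (!is.null(x$params))
    cat("  nominal:   ", paste(sprintf("%s=%g", x$param_names, x$params),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Piecewise-constant input signal
#'
#' Encodes an external, piecewise-constant input `u(t)` (for the sensor
#' construct: the extracellular inhibitor concentration, in nM). `levels[i]`
#' holds on `[breakpoints[i], breakpoints[i+1])`; evaluation before the first
#' or after the last breakpoint returns the corresponding boundary level.
#'
#' @param breakpoints strictly increasing times (seconds).
#' @param levels nonnegative level per interval; same length as `breakpoints`.
#' @return An object of class `input_signal`, callable via [input_level()].
#' @examples
#' pulse <- input_signal(c(0, 100, 300), c(0, 100, 0))
#' input_level(pulse, c(50, 150, 400))  # 0 100 0
#' @export
input_signal <- function(breakpoints = 0, levels = 0) {
  cc <- check_collector()
  cc$add(length(breakpoints) == length(levels),
         "breakpoints and levels must have equal length")
  cc$add(length(breakpoints) >= 1L, "need at least one breakpoint")
  cc$add(!is.unsorted(breakpoints, strictly = TRUE),
         "breakpoints must be strictly increasing")
  cc$add(all(levels >= 0), "levels must be nonnegative")
  cc$fail_if_any("invalid input signal")
  structure(list(breakpoints = as.numeric(breakpoints),
                 levels = as.numeric(levels)),
            class = "input_signal")
}

#' Evaluate an input signal
#' @param input an [input_signal()].
#' @param t numeric vector of times.
#' @return numeric vector of input levels.
#' @export
input_level <- function(input, t) {
  idx <- findInterval(t, input$breakpoints)
  input$levels[pmax(idx, 1L)]
}

#' @export
print.input_signal <- function(x, ...) {
  cat("<input_signal> levels",
      paste(sprintf("%g", x$levels), collapse = " | "),
      "switching at", paste(sprintf("%g", x$breakpoints), collapse = ", "),
      "sec\n")
  invisible(x)
}

#' Simulation setup
#'
#' @param x0 nonnegative initial state (nM).
#' @param horizon final time `T` in seconds (integration runs on `[0, T]`).
#' @param rtol,atol relative/absolute solver tolerances (stiff-capable
#'   `lsoda` integrator).
#' @param n_grid approximate number of output grid points over the horizon;
#'   points are apportioned to the segments between input breakpoints, at
#'   least 30 per segment, so the dense interpolant resolves each regime.
#' @return An object of class `sim_setup`.
#' @export
simulation_setup <- function(x0, horizon, rtol = 1e-8, atol = 1e-10,
                             n_grid = 400) {
  cc <- check_collector()
  cc$add(horizon > 0, "horizon must be > 0")
  cc$add(all(x0 >= 0), "x0 must be componentwise nonnegative")
  cc$add(rtol > 0 && atol > 0, "tolerances must be > 0")
  cc$add(n_grid >= 10, "n_grid must be at least 10")
  cc$fail_if_any("invalid simulation setup")
  structure(list(x0 = as.numeric(x0), horizon = as.numeric(horizon),
                 rtol = rtol, atol = atol, n_grid = as.integer(n_grid)),
            class = "sim_setup")
}

# Segment boundaries: input breakpoints (plus any caller-supplied
# non-smoothness times, e.g. feature-window edges) strictly inside (0, T),
# plus 0 and T.
segment_times <- function(input, horizon, extra_breaks = numeric()) {
  bp <- c(input$breakpoints, extra_breaks)
  inner <- bp[bp > 0 & bp < horizon]
  sort(unique(c(0, inner, horizon)))
}

#' Simulate a reaction network
#'
#' Integrates the reaction rate equation with the stiff-capable `lsoda`
#' solver. Integration is restarted at every breakpoint of the input signal
#' so that input discontinuities are hit exactly rather than smoothed over by
#' the step-size controller.
#'
#' @param network a [reaction_network()].
#' @param k full parameter vector (nonnegative); defaults to the network's
#'   nominal values.
#' @param setup a [simulation_setup()].
#' @param input an [input_signal()]; default: identically zero.
#' @return A `trajectory` object: fields `times` (grid on `[0, T]`), `states`
#'   (matrix, one row per time), and a dense cubic-spline interpolant
#'   evaluated with [trajectory_states()]. The interpolant reproduces the
#'   stored states exactly at grid points and is built per segment, so it
#'   never smooths across input discontinuities.
#' @export
simulate_network <- function(network, k = network$params, setup,
                             input = input_signal()) {
  if (is.null(k)) stop("no parameter vector given and network has no nominal values")
  if (length(k) != network$p)
    stop(sprintf("k has length %d, expected %d", length(k), network$p))
  if (any(k < 0)) stop("parameters must be nonnegative")
  if (length(setup$x0) != network$n)
    stop(sprintf("x0 has length %d, expected %d", length(setup$x0), network$n))

  N <- network$stoich
  rhs <- function(t, x, parms) {
    list(as.numeric(N %*% network$flux(x, k, parms$u, t)))
  }
  jac <- function(t, x, parms) {
    N %*% network$flux_jac_x(x, k, parms$u, t)
  }
  integrate_segments(rhs, jac, setup, input, n_state = network$n,
                     state_names = network$species)
}

# Shared piecewise integrator: runs `lsoda` segment by segment between input
# breakpoints and assembles a trajectory object with per-segment spline
# interpolants. Signals an `specmap_integration_failure` condition carrying
# the last reached time if the solver gives up.
integrate_segments <- function(rhs, jac, setup, input, n_state, state_names,
                               extra_breaks = numeric()) {
  seg <- segment_times(input, setup$horizon, extra_breaks)
  n_seg <- length(seg) - 1L
  lens <- diff(seg)
  pts <- pmax(30L, ceiling(setup$n_grid * lens / sum(lens)))

  x <- setup$x0
  seg_data <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    tt <- seq(seg[i], seg[i + 1L], length.out = pts[i])
    u <- input_level(input, (seg[i] + seg[i + 1L]) / 2)
    # tcrit: never step past the segment end -- the right-hand side may be
    # discontinuous there (input switches, feature windows opening/closing)
    args <- list(y = x, times = tt, func = rhs, parms = list(u = u),
                 rtol = setup$rtol, atol = setup$atol, maxsteps = 20000L,
                 tcrit = seg[i + 1L])
    if (!is.null(jac)) {
      args$jacfunc <- jac
      args$jactype <- "fullusr"
    }
    out <- try(do.call(deSolve::lsoda, args), silent = TRUE)
    failed <- inherits(out, "try-error") ||
      abs(unname(out[nrow(out), 1]) - seg[i + 1L]) >
        1e-8 * max(1, abs(seg[i + 1L]))
    if (failed) {
      t_last <- if (inherits(out, "try-error")) seg[i] else out[nrow(out), 1]
      cond <- structure(
        class = c("specmap_integration_failure", "error", "condition"),
        list(message = sprintf(
               "ODE integration failed at t = %g (of horizon %g)",
               t_last, setup$horizon),
             call = sys.call(-1), t_last = t_last))
      stop(cond)
    }
    states <- matrix(out[, -1, drop = FALSE], nrow = nrow(out))
    seg_data[[i]] <- list(t0 = seg[i], t1 = seg[i + 1L],
                          times = out[, 1], states = states,
                          splines = apply(states, 2, function(yy)
                            stats::splinefun(out[, 1], yy, method = "fmm")))
    x <- states[nrow(states), ]
  }

  times <- unlist(lapply(seq_len(n_seg), function(i) {
    tt <- seg_data[[i]]$times
    if (i < n_seg) tt[-length(tt)] else tt
  }))
  states <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
    ss <- seg_data[[i]]$states
    if (i < n_seg) ss[-nrow(ss), , drop = FALSE] else ss
  }))
  colnames(states) <- state_names
  structure(list(times = times, states = states, segments = seg_data,
                 horizon = setup$horizon, species = state_names),
            class = "trajectory")
}

#' Evaluate a trajectory interpolant
#'
#' @param traj a trajectory from [simulate_network()].
#' @param t numeric vector of times in `[0, T]`.
#' @return matrix with `length(t)` rows and one column per species.
#' @export
trajectory_states <- function(traj, t) {
  if (any(t < traj$times[1] - 1e-9) || any(t > traj$horizon + 1e-9))
    stop("evaluation time outside trajectory horizon")
  starts <- vapply(traj$segments, `[[`, numeric(1), "t0")
  idx <- pmin(pmax(findInterval(t, starts), 1L), length(traj$segments))
  out <- matrix(NA_real_, length(t), ncol(traj$states))
  for (i in unique(idx)) {
    sel <- idx == i
    sp <- traj$segments[[i]]$splines
    out[sel, ] <- vapply(sp, function(f) f(t[sel]), numeric(sum(sel)))
  }
  colnames(out) <- traj$species
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d species on [0, %g] sec, %d grid points\n",
              ncol(x$states), x$horizon, length(x$times)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Find a nonnegative steady state
#'
#' Relaxes the system by long-horizon integration at a constant input level,
#' then polishes the result with damped Newton iterations on
#' `N v(x, k, u) = 0` using the analytic Jacobian.
#'
#' @param network a [reaction_network()].
#' @param k parameter vector; defaults to nominal values.
#' @param input_level constant input level `u` (nM).
#' @param x_guess nonnegative starting state; default zero.
#' @param t_relax relaxation horizon in seconds before Newton polishing.
#' @param tol convergence threshold on the max-norm of the right-hand side.
#' @return steady state vector `x*` with `max |N v(x*, k, u)| < tol`.
#' @export
steady_state <- function(network, k = network$params, input_level = 0,
                         x_guess = rep(0, network$n), t_relax = 2e4,
                         tol = 1e-9) {
  if (any(x_guess < 0)) stop("x_guess must be nonnegative")
  setup <- simulation_setup(x_guess, t_relax, rtol = 1e-10, atol = 1e-12,
                            n_grid = 50)
  traj <- simulate_network(network, k, setup,
                           input_signal(0, input_level))
  x <- traj$states[nrow(traj$states), ]
  N <- network$stoich
  res <- function(x) as.numeric(N %*% network$flux(x, k, input_level, 0))
  for (it in 1:50) {
    r <- res(x)
    if (max(abs(r)) < tol) break
    J <- N %*% network$flux_jac_x(x, k, input_level, 0)
    dx <- try(solve(J, -r), silent = TRUE)
    if (inherits(dx, "try-error")) break
    alpha <- 1
    repeat {  # damped step, keep the iterate nonnegative
      x_new <- pmax(x + alpha * dx, 0)
      if (max(abs(res(x_new))) < max(abs(r)) || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    x <- x_new
  }
  if (max(abs(res(x))) >= tol) {
    cond <- structure(
      class = c("specmap_steady_state_failure", "error", "condition"),
      list(message = sprintf(
             "steady state not converged: residual %.3g (tol %.3g)",
             max(abs(res(x))), tol),
           call = sys.call(), x_last = x))
    stop(cond)
  }
  stats::setNames(pmax(x, 0), network$species)
}
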