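#' Designable parameter subset
#'
#' Selects which kinetic parameters are treated as design degrees of freedom;
#' the rest stay frozen at their nominal values. For the sensor case study
#' the designable rates are the inhibitor binding rate `k7` and the
#' dimer-promoter binding rate `k9` — the two rates an experimenter can
#' plausibly engineer via binding-site mutations.
#'
#' @param network a [reaction_network()].
#' @param params parameter names or indices (distinct, at least one).
#' @return An object of class `design_subset` with fields `idx` and `names`.
#' @export
design_subset <- function(network, params = c("k7", "k9")) {
  idx <- if (is.character(params)) match(params, network$param_names)
         else as.integer(params)
  cc <- check_collector()
  cc$add(!anyNA(idx), sprintf("unknown parameter(s): %s",
                              paste(params[is.na(idx)], collapse = ", ")))
  cc$add(length(idx) >= 1, "need at least one design parameter")
  cc$add(!anyDuplicated(idx), "design parameters must be distinct")
  cc$add(all(idx >= 1 & idx <= network$p, na.rm = TRUE),
         "design-parameter index out of range")
  cc$fail_if_any("invalid design subset")
  structure(list(idx = idx, names = network$param_names[idx],
                 p_design = length(idx)),
            class = "design_subset")
}

# Embed design coordinates into the full parameter vector.
embed_design <- function(network, k_design, subset) {
  k <- network$params
  if (is.null(k)) stop("network has no nominal parameters to embed into")
  if (length(k_design) != subset$p_design)
    stop("k_design length does not match design subset")
  k[subset$idx] <- k_design
  k
}

#' Solve the variational (forward-sensitivity) equations
#'
#' Jointly integrates the rate equation and the matrix variational equation
#' \deqn{\frac{d}{dt}\frac{\partial x}{\partial k} =
#'   N \frac{\partial v}{\partial x} \frac{\partial x}{\partial k}
#'   + N \frac{\partial v}{\partial k}, \qquad
#'   \frac{\partial x(0)}{\partial k} = 0,}
#' restricted to the columns of the design subset — `n + n * p_design`
#' coupled equations, restarted at input breakpoints.
#'
#' @param network a [reaction_network()].
#' @param k0 full parameter vector at the expansion point (defaults to
#'   nominal values).
#' @param setup a [simulation_setup()].
#' @param input an [input_signal()].
#' @param subset a [design_subset()].
#' @return list with `trajectory` (states only) and `sensitivities`: an
#'   array `[time, species, design parameter]` on the same grid.
#' @export
solve_variational <- function(network, k0 = network$params, setup,
                              input = input_signal(), subset) {
  if (any(k0 < 0)) stop("parameters must be nonnegative")
  n <- network$n; pd <- subset$p_design
  N <- network$stoich
  rhs <- function(t, y, parms) {
    x <- y[seq_len(n)]
    S <- matrix(y[n + seq_len(n * pd)], n, pd)
    Jx <- network$flux_jac_x(x, k0, parms$u, t)
    Jk <- network$flux_jac_k(x, k0, parms$u, t)[, subset$idx, drop = FALSE]
    dx <- N %*% network$flux(x, k0, parms$u, t)
    dS <- (N %*% Jx) %*% S + N %*% Jk
    list(c(as.numeric(dx), as.numeric(dS)))
  }
  setup_aug <- setup
  setup_aug$x0 <- c(setup$x0, numeric(n * pd))
  names_aug <- c(network$species,
                 as.vector(outer(network$species, subset$names, paste,
                                 sep = ".")))
  traj <- integrate_segments(rhs, jac = NULL, setup_aug, input,
                             n_state = n + n * pd, state_names = names_aug)
  nt <- length(traj$times)
  sens <- array(traj$states[, n + seq_len(n * pd)],
                dim = c(nt, n, pd),
                dimnames = list(NULL, network$species, subset$names))
  state_traj <- traj
  state_traj$states <- traj$states[, seq_len(n), drop = FALSE]
  colnames(state_traj$states) <- network$species
  state_traj$species <- network$species
  list(trajectory = state_traj, sensitivities = sens, times = traj$times,
       full = traj)
}

#' Linearize the parameter-to-feature map
#'
#' Computes the linearized forward map
#' \deqn{L = \frac{\partial F}{\partial k}\Big|_{k^0}
#'     = \int_0^T \frac{\partial g}{\partial x}\Big|_{x(s)}
#'       \frac{\partial x(s)}{\partial k} \, ds}
#' by one joint integration of the state equation, the variational equation,
#' the running feature sensitivities `dL(t)/dt = (dg/dx) (dx/dk)` with
#' `L(0) = 0`, and the running features `df/dt = g(t, x)`. The feature value
#' at the expansion point, `f0 = F(k0)`, falls out of the same integration.
#'
#' @param network a [reaction_network()].
#' @param kernel a [feature_kernel()].
#' @param k0 full parameter vector at the expansion point.
#' @param setup,input as in [simulate_network()].
#' @param subset a [design_subset()].
#' @return An object of class `linearized_map`: fields `L` (`m x p_design`),
#'   `f0`, `k0_design`, `k0_full`, `subset`, plus the setup metadata.
#' @export
linearize <- function(network, kernel, k0 = network$params, setup,
                      input = input_signal(), subset) {
  if (any(k0 < 0)) stop("parameters must be nonnegative")
  n <- network$n; pd <- subset$p_design; m <- kernel$m
  N <- network$stoich
  i_x <- seq_len(n)
  i_S <- n + seq_len(n * pd)
  i_L <- n + n * pd + seq_len(m * pd)
  i_f <- n + n * pd + m * pd + seq_len(m)
  rhs <- function(t, y, parms) {
    x <- y[i_x]
    S <- matrix(y[i_S], n, pd)
    Jx <- network$flux_jac_x(x, k0, parms$u, t)
    Jk <- network$flux_jac_k(x, k0, parms$u, t)[, subset$idx, drop = FALSE]
    Gx <- kernel$g_jac_x(t, x)
    dx <- N %*% network$flux(x, k0, parms$u, t)
    dS <- (N %*% Jx) %*% S + N %*% Jk
    dL <- Gx %*% S
    df <- kernel$g(t, x)
    list(c(as.numeric(dx), as.numeric(dS), as.numeric(dL), as.numeric(df)))
  }
  setup_aug <- setup
  setup_aug$x0 <- c(setup$x0, numeric(n * pd + m * pd + m))
  traj <- integrate_segments(rhs, jac = NULL, setup_aug, input,
                             n_state = length(setup_aug$x0),
                             state_names = paste0("y", seq_along(setup_aug$x0)),
                             extra_breaks = kernel$breaks)
  yT <- traj$states[nrow(traj$states), ]
  L <- matrix(yT[i_L], m, pd,
              dimnames = list(paste0("psi", seq_len(m)), subset$names))
  structure(list(L = L, f0 = unname(yT[i_f]),
                 k0_design = stats::setNames(k0[subset$idx], subset$names),
                 k0_full = k0, subset = subset,
                 horizon = setup$horizon,
                 rtol = setup$rtol, atol = setup$atol),
            class = "linearized_map")
}

#' @export
print.linearized_map <- function(x, ...) {
  cat(sprintf("<linearized_map> %d features x %d design parameters (%s)\n",
              nrow(x$L), ncol(x$L), paste(x$subset$names, collapse = ", ")))
  cat("  expansion point:", paste(sprintf("%s=%g", x$subset$names,
                                          x$k0_design), collapse = ", "), "\n")
  cat("  f0:", paste(sprintf("%.6g", x$f0), collapse = ", "), "\n")
  cat("  L:\n")
  print(x$L)
  invisible(x)
}

#' Forward map from design parameters to features
#'
#' The composition `F(k) = psi(phi(k))`: embed the design coordinates into
#' the full parameter vector, simulate, and evaluate the specification
#' functional by quadrature. Deterministic for fixed solver tolerances.
#'
#' @param network a [reaction_network()].
#' @param kernel a [feature_kernel()].
#' @param k_design design-parameter coordinates (nonnegative).
#' @param setup,input as in [simulate_network()].
#' @param subset a [design_subset()].
#' @return numeric feature vector of length `kernel$m`.
#' @export
forward_map <- function(network, kernel, k_design, setup,
                        input = input_signal(), subset) {
  if (any(k_design < 0))
    stop("design parameters must be nonnegative")
  k <- embed_design(network, k_design, subset)
  traj <- simulate_network(network, k, setup, input)
  evaluate_features(traj, kernel)
}
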