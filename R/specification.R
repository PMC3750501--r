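#' Feature kernel of a specification functional
#'
#' A behavioral specification functional maps a trajectory to an `m`-vector
#' of features
#' \deqn{\psi(x) = \int_0^T g(s, x(s))\, ds,}
#' where the kernel `g` is once-differentiable in the state. This container
#' holds `g`, its state Jacobian, and quadrature hints.
#'
#' @param m number of features.
#' @param g `function(t, x)` returning an `m`-vector; must vanish outside the
#'   declared support windows (if any).
#' @param g_jac_x `function(t, x)` returning the `m x n` matrix of partial
#'   derivatives of `g` with respect to the state. If `NULL`, central finite
#'   differences with step `1e-7 * max(|x_i|, 1)` are used.
#' @param support optional list of length `m`; element `i` is a matrix with
#'   rows `c(lo, hi)` giving the time windows outside which `g_i` is zero.
#'   `NULL` means full support on the horizon.
#' @param breaks optional times at which `g` is non-smooth in `t`
#'   (quadrature is restarted there).
#' @return An object of class `feature_kernel`.
#' @seealso [weighted_deviation_kernel()], [convolution_kernel()],
#'   [evaluate_features()]
#' @export
feature_kernel <- function(m, g, g_jac_x = NULL, support = NULL,
                           breaks = NULL) {
  stopifnot(m >= 1, is.function(g))
  if (is.null(g_jac_x)) {
    g_jac_x <- function(t, x) {
      n <- length(x)
      J <- matrix(0, m, n)
      for (i in seq_len(n)) {
        h <- 1e-7 * max(abs(x[i]), 1)
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        J[, i] <- (g(t, xp) - g(t, xm)) / (2 * h)
      }
      J
    }
  }
  if (!is.null(support)) {
    stopifnot(length(support) == m)
    support <- lapply(support, function(w) {
      w <- matrix(as.numeric(w), ncol = 2)
      if (any(w[, 1] >= w[, 2])) stop("support windows must have lo < hi")
      w
    })
  }
  structure(list(m = m, g = g, g_jac_x = g_jac_x, support = support,
                 breaks = sort(unique(as.numeric(breaks)))),
            class = "feature_kernel")
}

#' Weighted squared-deviation specification
#'
#' The case-study feature family: feature `i` integrates the squared
#' deviation of one species from a piecewise-constant target over a union of
#' time windows,
#' \deqn{\psi_i(x) = \int_0^T w_i(s)\,[x_{j(i)}(s) - x^*_i(s)]^2\, ds,}
#' with the weight `w_i(t) = 1` on the window union and `0` elsewhere. Units
#' of the features are nM^2 sec.
#'
#' For the sensor construct the intended reading is: a window during
#' inhibition where the dimer should sit near a low target, and a window
#' after washout where it should have recovered to a high target, with the
#' monomer constrained alongside.
#'
#' @param features list, one element per feature, each a list with:
#'   `species` (index or name), `windows` (matrix with rows `c(lo, hi)`, or a
#'   list of 2-vectors; typically two windows `[t1,t2]`, `[t3,t4]` with
#'   `t1 < t2 <= t3 < t4`), and `target` — a single value, one value per
#'   window, or a list `list(times=, values=)` describing a step function.
#' @param species character vector of the model's species names (resolves
#'   `species` given by name and fixes the state dimension).
#' @return A [feature_kernel()] with analytic state Jacobian
#'   `dg_i/dx_j = 2 w_i(t) (x_j - x*_i(t))`.
#' @export
weighted_deviation_kernel <- function(features, species) {
  m <- length(features)
  n <- length(species)
  cc <- check_collector()
  feats <- vector("list", m)
  for (i in seq_len(m)) {
    fe <- features[[i]]
    j <- if (is.character(fe$species)) match(fe$species, species)
         else as.integer(fe$species)
    cc$add(!is.na(j) && j >= 1 && j <= n,
           sprintf("feature %d: unknown species '%s'", i, fe$species))
    w <- fe$windows
    if (is.list(w)) w <- do.call(rbind, lapply(w, as.numeric))
    w <- matrix(as.numeric(w), ncol = 2)
    edges <- as.vector(t(w))
    cc$add(all(diff(edges) >= 0) && all(w[, 1] < w[, 2]),
           sprintf("feature %d: windows must be ordered with lo < hi", i))
    tgt <- fe$target
    if (is.list(tgt)) {
      tfun <- stats::stepfun(tgt$times, c(tgt$values[1], tgt$values))
      tbreaks <- tgt$times
    } else if (length(tgt) == nrow(w)) {
      vals <- as.numeric(tgt)
      tfun <- local({
        w_ <- w; v_ <- vals
        function(t) {
          idx <- rep(NA_integer_, length(t))
          for (r in seq_len(nrow(w_)))
            idx[t >= w_[r, 1] & t <= w_[r, 2]] <- r
          out <- v_[idx]
          out[is.na(out)] <- 0   # outside windows w = 0, value irrelevant
          out
        }
      })
      tbreaks <- numeric()
    } else if (length(tgt) == 1) {
      tfun <- local({v_ <- as.numeric(tgt); function(t) rep(v_, length(t))})
      tbreaks <- numeric()
    } else {
      cc$add(FALSE, sprintf("feature %d: malformed target", i))
      tfun <- function(t) rep(0, length(t)); tbreaks <- numeric()
    }
    cc$add(all(tfun(rowMeans(w)) >= 0),
           sprintf("feature %d: targets must be nonnegative", i))
    feats[[i]] <- list(j = j, w = w, tfun = tfun, tbreaks = tbreaks)
  }
  cc$fail_if_any("invalid weighted-deviation specification")

  in_windows <- function(fe, t) {
    hit <- rep(FALSE, length(t))
    for (r in seq_len(nrow(fe$w)))
      hit <- hit | (t >= fe$w[r, 1] & t <= fe$w[r, 2])
    hit
  }
  g <- function(t, x) {
    vapply(feats, function(fe) {
      if (in_windows(fe, t)) (x[fe$j] - fe$tfun(t))^2 else 0
    }, numeric(1))
  }
  g_jac_x <- function(t, x) {
    J <- matrix(0, m, n)
    for (i in seq_len(m)) {
      fe <- feats[[i]]
      if (in_windows(fe, t)) J[i, fe$j] <- 2 * (x[fe$j] - fe$tfun(t))
    }
    J
  }
  kern <- feature_kernel(
    m = m, g = g, g_jac_x = g_jac_x,
    support = lapply(feats, `[[`, "w"),
    breaks = unlist(lapply(feats, function(fe) c(as.vector(fe$w), fe$tbreaks))))
  kern$deviation_spec <- feats
  kern
}

#' Convolution feature kernel
#'
#' The tractable special case `g(t, x) = h(T - t) x`: one feature per
#' species, each the convolution of that species with the time weight `h`.
#' With `h` identically 1 this yields the per-species time integrals; a
#' narrow box around 0 approximates point evaluation `x(T)`.
#'
#' @param h `function(s)` time weight, integrable on `[0, T]`; vectorized.
#' @param horizon `T` in seconds.
#' @param n number of species (feature count `m = n`).
#' @param support optional time window (or matrix of windows) outside which
#'   `h(T - t)` vanishes — a quadrature hint for sharply localized weights
#'   such as narrow boxes approximating point evaluation.
#' @return A [feature_kernel()] with `dg/dx = h(T - t) I`.
#' @export
convolution_kernel <- function(h, horizon, n, support = NULL) {
  stopifnot(is.function(h), horizon > 0, n >= 1)
  if (!is.null(support)) {
    support <- matrix(as.numeric(support), ncol = 2)
    support <- rep(list(support), n)
  }
  feature_kernel(
    m = n,
    g = function(t, x) h(horizon - t) * x,
    g_jac_x = function(t, x) diag(h(horizon - t), n, n),
    support = support,
    breaks = if (!is.null(support)) as.vector(support[[1]]))
}

#' Evaluate a specification functional on a trajectory
#'
#' Computes \eqn{\psi(x) = \int_0^T g(s, x(s)) ds} by adaptive quadrature on
#' the trajectory's dense interpolant. The integration domain is split at
#' every input-signal segment boundary, declared kernel break, and support
#' window edge, so the adaptive rule only ever sees smooth integrands; each
#' feature is integrated only over its declared support.
#'
#' @param traj trajectory from [simulate_network()].
#' @param kernel a [feature_kernel()].
#' @param rel_tol per-piece relative quadrature tolerance.
#' @return numeric feature vector of length `kernel$m`.
#' @export
evaluate_features <- function(traj, kernel, rel_tol = 1e-10) {
  T_ <- traj$horizon
  if (!is.null(kernel$support)) {
    hi <- max(vapply(kernel$support, max, numeric(1)))
    if (hi > T_ + 1e-9)
      stop(sprintf(
        "kernel support extends to t = %g beyond trajectory horizon %g",
        hi, T_))
  }
  seg_edges <- vapply(traj$segments, `[[`, numeric(1), "t0")
  cuts <- sort(unique(c(0, T_, seg_edges,
                        kernel$breaks[kernel$breaks > 0 & kernel$breaks < T_])))

  f <- numeric(kernel$m)
  for (i in seq_len(kernel$m)) {
    dom <- if (is.null(kernel$support)) matrix(c(0, T_), 1)
           else kernel$support[[i]]
    gi <- function(t) {
      X <- trajectory_states(traj, t)
      vapply(seq_along(t), function(r) kernel$g(t[r], X[r, ])[i], numeric(1))
    }
    total <- 0
    for (r in seq_len(nrow(dom))) {
      lo <- max(dom[r, 1], 0); hi <- min(dom[r, 2], T_)
      if (hi <= lo) next
      inner <- cuts[cuts > lo & cuts < hi]
      pieces <- cbind(c(lo, inner), c(inner, hi))
      for (pp in seq_len(nrow(pieces))) {
        total <- total + stats::integrate(
          gi, pieces[pp, 1], pieces[pp, 2],
          rel.tol = rel_tol, abs.tol = 0,
          subdivisions = 200L, stop.on.error = FALSE)$value
      }
    }
    f[i] <- total
  }
  f
}

# Feature vector via augmented ODE states: appends df/dt = g(t, x) to the
# rate equation and reads psi at T. Used as an independent route to
# cross-check the quadrature path, and shares its machinery with linearize().
features_via_ode <- function(network, kernel, k = network$params, setup,
                             input = input_signal()) {
  n <- network$n; m <- kernel$m
  N <- network$stoich
  rhs <- function(t, y, parms) {
    x <- y[seq_len(n)]
    list(c(as.numeric(N %*% network$flux(x, k, parms$u, t)),
           kernel$g(t, x)))
  }
  setup_aug <- setup
  setup_aug$x0 <- c(setup$x0, numeric(m))
  traj <- integrate_segments(rhs, jac = NULL, setup_aug, input,
                             n_state = n + m,
                             state_names = c(network$species,
                                             paste0("psi", seq_len(m))),
                             extra_breaks = kernel$breaks)
  unname(traj$states[nrow(traj$states), n + seq_len(m)])
}
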