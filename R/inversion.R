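#' Moore-Penrose pseudoinverse via SVD
#'
#' Computes `L+` from the singular value decomposition `L = U S V'`, zeroing
#' singular values below `cutoff_rel * max(S)`. This equals the Tikhonov
#' limit \eqn{\lim_{\lambda \to 0}(L'L + \lambda I)^{-1} L'}, which exists
#' even when `L'L` is singular (fewer features than design parameters, or
#' rank deficiency); the SVD route with a relative cutoff is the rank-safe
#' way to evaluate that limit. [pinv_limit()] implements the regularized
#' form directly for cross-checking.
#'
#' @param L numeric matrix (`m x p`).
#' @param cutoff_rel relative singular-value cutoff.
#' @return An object of class `pseudo_inverse`: `Ldag` (`p x m`), the SVD
#'   factors `u`, `d`, `v`, the effective `rank`, and `cutoff`.
#' @export
pseudo_inverse <- function(L, cutoff_rel = 1e-12) {
  L <- as.matrix(L)
  stopifnot(all(is.finite(L)), length(L) > 0)
  sv <- svd(L)
  cutoff <- cutoff_rel * max(sv$d, 0)
  keep <- sv$d > cutoff
  dinv <- ifelse(keep, 1 / sv$d, 0)
  Ldag <- sv$v %*% (dinv * t(sv$u))
  structure(list(Ldag = Ldag, u = sv$u, d = sv$d, v = sv$v,
                 rank = sum(keep), cutoff = cutoff, L = L),
            class = "pseudo_inverse")
}

#' Regularized pseudoinverse (Tikhonov form)
#'
#' Evaluates \eqn{(L'L + \lambda I)^{-1} L'} at a fixed `lambda > 0`. As
#' `lambda` decreases this converges to the Moore-Penrose pseudoinverse;
#' kept as an independent reference for [pseudo_inverse()].
#'
#' @param L numeric matrix.
#' @param lambda ridge parameter.
#' @return `p x m` matrix.
#' @export
pinv_limit <- function(L, lambda) {
  L <- as.matrix(L)
  p <- ncol(L)
  solve(crossprod(L) + diag(lambda, p), t(L))
}

#' @export
print.pseudo_inverse <- function(x, ...) {
  cat(sprintf("<pseudo_inverse> %d x %d, rank %d, singular values: %s\n",
              nrow(x$Ldag), ncol(x$Ldag), x$rank,
              paste(sprintf("%.4g", x$d), collapse = ", ")))
  invisible(x)
}

#' Feature ball
#'
#' Euclidean ball `B(f0, delta)` in feature space: the patch of the
#' specification around an expansion feature point that is mapped back to
#' parameter space in one linearized step.
#'
#' @param center feature vector `f0`.
#' @param radius `delta` (same units as the features); `0` gives the
#'   degenerate single-point ball.
#' @return object of class `feature_ball`.
#' @export
feature_ball <- function(center, radius) {
  stopifnot(radius >= 0, all(is.finite(center)))
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "feature_ball")
}

#' @param ball a [feature_ball()].
#' @param f feature vector or matrix (rows = points).
#' @return logical vector of ball membership.
#' @rdname feature_ball
#' @export
in_ball <- function(ball, f) {
  f <- if (is.matrix(f)) f else matrix(f, nrow = 1)
  sqrt(colSums((t(f) - ball$center)^2)) <= ball$radius
}

#' Map a feature ball back to a parameter ellipsoid
#'
#' The image of `B(f0, delta)` under the affine back-map
#' `k = k0 + L+ (f - f0)` is an ellipsoid: the SVD writes `L+` as a rotation,
#' a scaling and another rotation, so the ball's image has principal
#' semi-axes `delta / sigma_i(L)` along the right-singular directions of `L`
#' (degenerate — zero extent — along directions cut off in the
#' pseudoinverse).
#'
#' @param pinv a [pseudo_inverse()] of the linearized map.
#' @param ball a [feature_ball()] centered at the expansion feature point.
#' @param k0 design-parameter coordinates of the expansion point.
#' @return object of class `parameter_ellipsoid` with fields `center`,
#'   `semi_axes`, `axes` (unit column vectors), `delta`, and the generating
#'   `pinv`/`f0`.
#' @export
map_ball <- function(pinv, ball, k0) {
  stopifnot(length(k0) == nrow(pinv$Ldag),
            length(ball$center) == ncol(pinv$Ldag))
  semi <- ifelse(pinv$d > pinv$cutoff, ball$radius / pinv$d, 0)
  structure(list(center = as.numeric(k0),
                 semi_axes = semi,
                 axes = pinv$v,
                 delta = ball$radius,
                 f0 = ball$center,
                 pinv = pinv),
            class = "parameter_ellipsoid")
}

#' @export
print.parameter_ellipsoid <- function(x, ...) {
  cat(sprintf("<parameter_ellipsoid> center (%s), semi-axes (%s)\n",
              paste(sprintf("%.4g", x$center), collapse = ", "),
              paste(sprintf("%.4g", x$semi_axes), collapse = ", ")))
  invisible(x)
}

#' Ellipsoid membership
#'
#' A parameter point belongs to the ellipsoid when it is the back-mapped
#' image of some feature point of the generating ball; equivalently, its
#' coordinates in the right-singular basis scaled by the singular values of
#' `L` lie within `delta`, and it has no component along cut-off directions.
#'
#' @param ell a [map_ball()] result.
#' @param k parameter point (or matrix, rows = points).
#' @param tol numeric slack on the quadratic form and the null components.
#' @return logical vector.
#' @export
in_ellipsoid <- function(ell, k, tol = 1e-8) {
  K <- if (is.matrix(k)) k else matrix(k, nrow = 1)
  dk <- t(K) - ell$center
  z <- t(ell$axes) %*% dk                # coordinates in singular basis
  d <- ell$pinv$d
  keep <- d > ell$pinv$cutoff
  r2 <- colSums((z[keep, , drop = FALSE] * d[keep])^2)
  # no displacement allowed outside the image span of L+
  resid <- dk - ell$axes[, keep, drop = FALSE] %*% z[keep, , drop = FALSE]
  scale <- 1 + sqrt(colSums(dk^2))
  sqrt(r2) <= ell$delta * (1 + tol) & sqrt(colSums(resid^2)) <= tol * scale
}

#' Sample parameter sets from an ellipsoid
#'
#' Draws feature points uniformly in the generating ball (isotropic Gaussian
#' direction, radius scaled by `U^(1/m)`) and maps them back with `L+`.
#' Every returned point therefore lies in the ellipsoid by construction.
#' Draws whose back-mapped parameters have a negative coordinate are
#' rejected and resampled; the rejection count is attached. A rejection
#' rate above 90% (the ellipsoid essentially leaves the positive orthant)
#' raises an error.
#'
#' @param ell a [map_ball()] result.
#' @param n number of points.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return `n x p_design` matrix of parameter points, with attributes
#'   `features` (the generating feature draws) and `n_rejected`.
#' @export
sample_ellipsoid <- function(ell, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    m <- length(ell$f0)
    p <- length(ell$center)
    K <- matrix(NA_real_, n, p)
    FF <- matrix(NA_real_, n, m)
    rejected <- 0L
    for (i in seq_len(n)) {
      repeat {
        if (ell$delta == 0) {
          f <- ell$f0
        } else {
          u <- stats::rnorm(m)
          f <- ell$f0 + ell$delta * stats::runif(1)^(1 / m) * u / vnorm(u)
        }
        k <- ell$center + as.numeric(ell$pinv$Ldag %*% (f - ell$f0))
        if (all(k >= 0)) break
        rejected <- rejected + 1L
        if (rejected > 9 * n + 10)
          stop("ellipsoid rejection rate above 90%: region leaves the ",
               "positive parameter orthant")
      }
      K[i, ] <- k
      FF[i, ] <- f
    }
    if (rejected > 0)   # warn only when rejections dominate the draws
      sm_log(if (rejected > n + 4L) "WARN" else "INFO",
             "sample_ellipsoid: %d draws rejected (negative rates)", rejected)
    structure(K, features = FF, n_rejected = rejected)
  })
}

#' Secant (rank-one) update of a linearized map
#'
#' Given one extra evaluation `F(ki)` of the forward map, returns the matrix
#' closest to `L` in Frobenius norm that interpolates it:
#' \deqn{\tilde L = L + \frac{(\Delta F - L \Delta k)\,\Delta k'}
#'       {\|\Delta k\|^2},}
#' with \eqn{\Delta k = k^i - k^0}, \eqn{\Delta F = F(k^i) - f^0}. The
#' update satisfies the consistency property
#' \eqn{\tilde L (k^i - k^0) = F(k^i) - f^0} exactly, and the size of the
#' correction measures the local nonlinearity of `F`.
#'
#' @param L `m x p` matrix.
#' @param k0,f0 expansion point and its feature value.
#' @param ki,Fki the extra parameter point and its (exact) feature value.
#' @return the updated `m x p` matrix.
#' @export
rank_one_update <- function(L, k0, f0, ki, Fki) {
  dk <- as.numeric(ki) - as.numeric(k0)
  dF <- as.numeric(Fki) - as.numeric(f0)
  nk2 <- sum(dk^2)
  if (sqrt(nk2) < 1e-14)
    stop("degenerate rank-one update: ||ki - k0|| below 1e-14")
  L + tcrossprod(dF - as.numeric(L %*% dk), dk) / nk2
}

#' Estimate the nonlinearity bound rho(delta)
#'
#' For each radius in `delta_grid`, draws feature points in the ball
#' `B(f0, delta)`, maps them back through `L+`, evaluates the true forward
#' map there, forms the secant update, and records the largest Frobenius
#' distance `||Ltilde - L||_F` observed. A running maximum across the grid
#' enforces monotonicity. Being a sampled maximum, the estimate is a lower
#' bound on the true supremum; downstream guarantees are therefore
#' statistical rather than certified.
#'
#' @param network,kernel,setup,input,subset forward-map ingredients.
#' @param linmap a [linearize()] result (expansion point).
#' @param delta_grid increasing vector of ball radii.
#' @param n_samples draws per radius.
#' @param seed integer seed.
#' @param pinv optional precomputed [pseudo_inverse()] of `linmap$L`.
#' @return object of class `rho_estimate`: `delta_grid`, `rho_values`,
#'   `n_samples`, `seed`, `n_failed`.
#' @export
estimate_rho <- function(network, kernel, linmap, delta_grid,
                         n_samples = 20, seed = NULL, setup,
                         input = input_signal(), subset = linmap$subset,
                         pinv = NULL) {
  stopifnot(!is.unsorted(delta_grid, strictly = TRUE), all(delta_grid > 0),
            n_samples >= 1)
  if (is.null(pinv)) pinv <- pseudo_inverse(linmap$L)
  k0 <- linmap$k0_design
  f0 <- linmap$f0
  with_seed(seed, {
    rho <- numeric(length(delta_grid))
    failed <- 0L
    run_max <- 0
    for (gi in seq_along(delta_grid)) {
      ell <- map_ball(pinv, feature_ball(f0, delta_grid[gi]), k0)
      worst <- 0
      ok <- 0L
      for (s in seq_len(n_samples)) {
        ki <- tryCatch(drop(sample_ellipsoid(ell, 1)), error = function(e) NULL)
        if (is.null(ki)) { failed <- failed + 1L; next }
        if (vnorm(ki - k0) < 1e-12) next  # degenerate secant, skip
        Fki <- tryCatch(
          forward_map(network, kernel, ki, setup, input, subset),
          specmap_integration_failure = function(e) {
            sm_log("WARN", "rho sample skipped: %s", conditionMessage(e))
            NULL
          })
        if (is.null(Fki)) { failed <- failed + 1L; next }
        Lt <- rank_one_update(linmap$L, k0, f0, ki, Fki)
        worst <- max(worst, fnorm(Lt - linmap$L))
        ok <- ok + 1L
      }
      if (ok == 0L && gi == length(delta_grid) && run_max == 0)
        stop("all rho samples failed")
      run_max <- max(run_max, worst)
      rho[gi] <- run_max
    }
    structure(list(delta_grid = delta_grid, rho_values = rho,
                   n_samples = n_samples, seed = seed, n_failed = failed),
              class = "rho_estimate")
  })
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat("<rho_estimate>\n")
  print(data.frame(delta = x$delta_grid, rho = x$rho_values))
  invisible(x)
}

# Monotone interpolant of the rho estimate: linear through (0, 0) and the
# grid, constant beyond the last grid point.
rho_fun <- function(rho) {
  xs <- c(0, rho$delta_grid)
  ys <- c(0, rho$rho_values)
  function(d) stats::approx(xs, ys, xout = pmin(d, max(xs)),
                            rule = 2)$y
}

#' Maximal admissible feature-ball radius
#'
#' Solves
#' \deqn{\max_\delta \ \delta \quad \text{s.t.} \quad
#'   \rho(\delta)\,\sigma_{\max}(L^+)\,\delta \le \varepsilon,}
#' the worst case over the ball of the robust error bound
#' \eqn{\rho(\delta)\|L^+(f - f^0)\|}, using bisection on the monotone
#' interpolant of the sampled `rho`. The simplified bound assumes `L` has
#' full row rank (`L L+ = I`); otherwise the two-term bound
#' \eqn{\|(L L^+ - I)(f - f^0)\| + \rho(\delta)\|L^+(f - f^0)\|} is used,
#' with its worst ball direction bounded by
#' \eqn{\delta\,\sigma_{\max}(L L^+ - I) + \rho(\delta)\,\delta\,
#' \sigma_{\max}(L^+)}.
#'
#' @param rho a [estimate_rho()] result.
#' @param pinv a [pseudo_inverse()].
#' @param eps reverse-forward error tolerance (feature units).
#' @param delta_cap upper bound on the radius.
#' @return the selected radius `delta*` (lower bisection bracket, hence
#'   conservative).
#' @export
max_ball_radius <- function(rho, pinv, eps, delta_cap) {
  stopifnot(eps >= 0, delta_cap > 0)
  rf <- rho_fun(rho)
  smax <- max(ifelse(pinv$d > pinv$cutoff, 1 / pinv$d, 0))
  full_row_rank <- pinv$rank == ncol(pinv$Ldag)  # rank == m
  if (full_row_rank) {
    bound <- function(d) rf(d) * smax * d
  } else {
    P <- pinv$L %*% pinv$Ldag
    mis <- svd(P - diag(nrow(P)))$d[1]
    bound <- function(d) mis * d + rf(d) * smax * d
  }
  if (eps == 0) {
    if (bound(delta_cap) > 0) {
      warning("eps = 0 with positive nonlinearity bound: radius is 0")
      return(0)
    }
    return(delta_cap)
  }
  if (bound(delta_cap) <= eps) return(delta_cap)
  lo <- 0; hi <- delta_cap
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (bound(mid) <= eps) lo <- mid else hi <- mid
  }
  lo
}

#' Reverse-forward error at a feature point
#'
#' Maps the feature point back to parameters with the linearized inverse,
#' re-simulates, and measures how far the realized features land from the
#' request: `||F(k0 + L+ (f - f0)) - f||`. This is the error the ball-radius
#' selection controls.
#'
#' @param network,kernel,setup,input,subset forward-map ingredients.
#' @param linmap a [linearize()] result.
#' @param pinv its [pseudo_inverse()].
#' @param f requested feature vector.
#' @param negative how to treat back-mapped parameters with negative
#'   coordinates: `"reject"` returns `NA` with attribute
#'   `rejected = TRUE`; `"clamp"` evaluates at the componentwise
#'   nonnegative part and flags `clamped = TRUE`.
#' @return the Euclidean error (scalar), possibly with flags.
#' @export
reverse_forward_error <- function(network, kernel, linmap, pinv, f, setup,
                                  input = input_signal(),
                                  subset = linmap$subset,
                                  negative = c("reject", "clamp")) {
  negative <- match.arg(negative)
  k <- linmap$k0_design + as.numeric(pinv$Ldag %*% (f - linmap$f0))
  clamped <- FALSE
  if (any(k < 0)) {
    if (negative == "reject") {
      sm_log("WARN", "reverse_forward_error: negative back-mapped rate, rejected")
      return(structure(NA_real_, rejected = TRUE))
    }
    k <- pmax(k, 0)
    clamped <- TRUE
  }
  Fk <- forward_map(network, kernel, k, setup, input, subset)
  structure(vnorm(Fk - f), clamped = if (clamped) TRUE else NULL)
}
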