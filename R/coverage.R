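#' Rectangular specification region in feature space
#'
#' Axis-aligned box `S` of admissible feature values — the quantitative
#' behavioral specification the covering algorithm fills with feature balls.
#'
#' @param lo,hi numeric vectors of per-feature bounds (`lo < hi`), in the
#'   units of the features.
#' @return object of class `spec_region` with fields `lo`, `hi`, `m`,
#'   `diam` (Euclidean box diagonal).
#' @export
specification_region <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  cc <- check_collector()
  cc$add(length(lo) == length(hi), "lo and hi must have equal length")
  cc$add(all(lo < hi), "need lo < hi on every axis")
  cc$fail_if_any("invalid specification region")
  structure(list(lo = lo, hi = hi, m = length(lo),
                 diam = sqrt(sum((hi - lo)^2))),
            class = "spec_region")
}

#' @param region a [specification_region()].
#' @param f feature vector or matrix (rows = points).
#' @rdname specification_region
#' @export
in_region <- function(region, f) {
  F_ <- if (is.matrix(f)) f else matrix(f, nrow = 1)
  apply(F_, 1, function(r) all(r >= region$lo & r <= region$hi))
}

# uniform points in the box, one row per draw (uses current RNG stream)
region_uniform <- function(region, n) {
  sapply(seq_len(region$m), function(j)
    stats::runif(n, region$lo[j], region$hi[j]))
}

#' Monte-Carlo coverage of a region by a set of balls
#'
#' Fraction of uniform points of the box lying in the union of the balls.
#'
#' @param region a [specification_region()].
#' @param balls list of [feature_ball()]s.
#' @param n_mc number of Monte-Carlo points (at least 100).
#' @param seed integer seed.
#' @return coverage fraction in `[0, 1]`, with attributes `se` (binomial
#'   standard error) and `se_bound` (`0.5 / sqrt(n_mc)`).
#' @export
estimate_coverage <- function(region, balls, n_mc = 1e5, seed = NULL) {
  stopifnot(n_mc >= 100)
  with_seed(seed, {
    pts <- region_uniform(region, n_mc)
    covered <- rep(FALSE, n_mc)
    for (b in balls)
      covered <- covered | in_ball(b, pts)
    p <- mean(covered)
    structure(p, se = sqrt(p * (1 - p) / n_mc), se_bound = 0.5 / sqrt(n_mc))
  })
}

#' Ball-walk proposal for the next expansion center
#'
#' Proposes the next feature-space expansion point: uniform draws in a
#' step-ball around the current center, kept only if inside the region.
#' If `max_tries` in-region proposals in a row land in already-covered
#' territory, the walk restarts from a uniform point of the uncovered part
#' of the region (rejection sampling); if no uncovered point can be found
#' the region is taken to be fully covered.
#'
#' @param current a [feature_ball()] (the walk state).
#' @param region a [specification_region()].
#' @param covered_test `function(f)` returning `TRUE` when `f` is already
#'   covered.
#' @param step proposal radius; defaults to the current ball's radius.
#' @param max_tries covered-proposal budget before restarting.
#' @param seed optional seed (otherwise continues the current RNG stream).
#' @return list with `status` (`"ok"`, `"restart"`, or `"done"`) and
#'   `point` (the proposed center, `NULL` when done).
#' @export
ball_walk_next <- function(current, region, covered_test,
                           step = current$radius, max_tries = 20,
                           seed = NULL) {
  with_seed(seed, {
    m <- region$m
    for (i in seq_len(max_tries * 5)) {
      u <- stats::rnorm(m)
      f <- current$center + step * stats::runif(1)^(1 / m) * u / vnorm(u)
      if (!in_region(region, f)) next
      if (!covered_test(f))
        return(list(status = "ok", point = f))
      if (i >= max_tries) break
    }
    for (i in seq_len(500)) {   # restart from the uncovered remainder
      f <- drop(region_uniform(region, 1))
      if (!covered_test(f))
        return(list(status = "restart", point = f))
    }
    list(status = "done", point = NULL)
  })
}

# Damped Gauss-Newton pull-back of a feature target: find k with
# F(k) ~ f_target, relinearizing at each iterate. Returns the final
# linearized map (expansion point k, f0 = F(k)) or NULL on failure.
gauss_newton_pullback <- function(f_target, k_start, network, kernel, setup,
                                  input, subset, tol, max_iter = 25) {
  k <- pmax(k_start, 0)
  lin <- linearize(network, kernel, embed_design(network, k, subset),
                   setup, input, subset)
  best <- lin
  for (it in seq_len(max_iter)) {
    r <- f_target - lin$f0
    if (vnorm(r) <= tol) return(lin)
    pinv <- pseudo_inverse(lin$L)
    dk <- as.numeric(pinv$Ldag %*% r)
    alpha <- 1
    improved <- FALSE
    for (h in 1:6) {            # step halving on the residual norm
      k_new <- pmax(k + alpha * dk, 0)
      lin_new <- tryCatch(
        linearize(network, kernel, embed_design(network, k_new, subset),
                  setup, input, subset),
        specmap_integration_failure = function(e) NULL)
      if (!is.null(lin_new) && vnorm(f_target - lin_new$f0) < vnorm(r)) {
        k <- k_new; lin <- lin_new; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    if (vnorm(f_target - lin$f0) < vnorm(f_target - best$f0)) best <- lin
  }
  if (vnorm(f_target - best$f0) <= tol) best else NULL
}

#' Cover a specification region with error-controlled feature balls
#'
#' The main covering loop: starting from the feature image of the nominal
#' design, repeatedly (1) pull the next proposed center back to parameter
#' space by damped Gauss-Newton on the linearized map, (2) linearize there,
#' (3) estimate the local nonlinearity bound `rho(delta)` by secant
#' sampling, (4) choose the largest ball radius keeping the worst-case
#' reverse-forward error below `eps`, and (5) record the ball and its
#' back-mapped parameter ellipsoid. Next centers come from a ball walk
#' through the uncovered part of the region, so consecutive balls overlap.
#' Balls adapt: in strongly nonlinear corners of `S` the radius selection
#' forces small balls, in near-linear parts large ones.
#'
#' The run stops when the Monte-Carlo coverage estimate (a fixed point set
#' drawn once per run) reaches `coverage_target`, when `max_balls` is
#' exhausted, or when no uncovered point remains. Fully deterministic for a
#' fixed seed.
#'
#' @param region a [specification_region()].
#' @param network,kernel,setup,input,subset forward-map ingredients.
#' @param eps reverse-forward error tolerance (feature units).
#' @param max_balls ball budget.
#' @param seed integer seed driving every random stage.
#' @param rho_config list: `n_delta` radii in the grid and `n_samples`
#'   secant draws per radius for [estimate_rho()].
#' @param delta_cap largest allowed radius; default half the box diagonal.
#' @param delta_min_frac skip centers whose admissible radius falls below
#'   this fraction of the box diagonal (prevents stalling on degenerate
#'   corners).
#' @param coverage_target stop once this coverage fraction is reached.
#' @param n_mc Monte-Carlo points for the coverage estimate.
#' @param gn_tol_frac Gauss-Newton convergence tolerance as a fraction of
#'   the box diagonal.
#' @param n_err_samples reverse-forward error draws recorded per ball.
#' @return object of class `coverage_result`: `balls`, `ellipsoids`,
#'   `centers_k` (design coordinates per ball), `rho` (per-ball
#'   [estimate_rho()] results), `error_stats` (per-ball median/max observed
#'   reverse-forward error), `coverage_fraction`, `coverage_se`,
#'   `coverage_path` (fraction after each ball), `n_mc`, `seed`,
#'   `n_balls`, `eps`, and `complete` (`FALSE` when the budget ran out
#'   first).
#' @export
cover_region <- function(region, network, kernel, eps, max_balls = 50,
                         seed = 1, setup, input = input_signal(), subset,
                         rho_config = list(n_delta = 4, n_samples = 10),
                         delta_cap = NULL, delta_min_frac = 1e-3,
                         coverage_target = 0.98, n_mc = 1e5,
                         gn_tol_frac = 1e-3, n_err_samples = 5) {
  stopifnot(eps > 0, max_balls >= 1)
  delta_cap <- delta_cap %||% (region$diam / 2)
  delta_min <- delta_min_frac * region$diam
  gn_tol <- gn_tol_frac * region$diam

  with_seed(seed, {
    mc_pts <- region_uniform(region, n_mc)    # fixed evaluation point set
    covered <- rep(FALSE, n_mc)

    balls <- list(); ells <- list(); rhos <- list(); stats_ <- list()
    centers_k <- list()
    cov_path <- numeric(0)
    probed <- list()

    # first center: nominal image, clamped into S if outside
    k_nom <- network$params[subset$idx]
    f_nom <- forward_map(network, kernel, k_nom, setup, input, subset)
    target <- pmin(pmax(f_nom, region$lo), region$hi)
    walk <- NULL
    attempts <- 0L

    while (length(balls) < max_balls && attempts < 6L * max_balls) {
      attempts <- attempts + 1L

      if (!is.null(walk)) {
        covered_test <- function(f) {
          any(vapply(balls, function(b) in_ball(b, f), logical(1)))
        }
        prop <- ball_walk_next(walk, region, covered_test)
        if (prop$status == "done") break
        target <- prop$point
      }
      probed[[length(probed) + 1L]] <- target

      # warm start from the nearest recorded center (feature distance)
      k_start <- k_nom
      if (length(balls)) {
        d2 <- vapply(balls, function(b) sum((b$center - target)^2), numeric(1))
        k_start <- centers_k[[which.min(d2)]]
      }
      lin <- gauss_newton_pullback(target, k_start, network, kernel, setup,
                                   input, subset, tol = gn_tol)
      if (is.null(lin) || !in_region(region, lin$f0)) {
        if (is.null(walk) && length(balls) == 0L) {
          if (is.null(lin)) stop(
            "unreachable region: Gauss-Newton failed at the initial center; ",
            "probed feature points: ",
            paste(vapply(probed, function(p) paste(signif(p, 6),
                  collapse = "/"), character(1)), collapse = "; "))
          # nominal image achieved but outside S: walk from its clamp
          walk <- feature_ball(target, region$diam / 10)
          next
        }
        walk <- feature_ball(target, max(delta_min * 10, region$diam / 10))
        sm_log("INFO", "center at (%s) not reachable, re-proposing",
               paste(signif(target, 4), collapse = ", "))
        next
      }

      pinv <- pseudo_inverse(lin$L)
      grid <- delta_cap * rev(1 / 2^(seq_len(rho_config$n_delta) - 1))
      rho <- estimate_rho(network, kernel, lin, grid,
                          n_samples = rho_config$n_samples,
                          setup = setup, input = input, subset = subset,
                          pinv = pinv)
      delta <- max_ball_radius(rho, pinv, eps, delta_cap)
      if (delta < delta_min) {
        sm_log("INFO", "admissible radius %.3g below minimum, skipping", delta)
        walk <- feature_ball(lin$f0, max(delta_min * 10, delta_cap / 10))
        next
      }

      ball <- feature_ball(lin$f0, delta)
      ell <- map_ball(pinv, ball, lin$k0_design)

      errs <- rep(NA_real_, n_err_samples)
      if (n_err_samples > 0) {
        smp <- tryCatch(sample_ellipsoid(ell, n_err_samples),
                        error = function(e) NULL)
        if (!is.null(smp)) {
          fs <- attr(smp, "features")
          errs <- vapply(seq_len(n_err_samples), function(i)
            as.numeric(reverse_forward_error(network, kernel, lin, pinv,
                                             fs[i, ], setup, input, subset)),
            numeric(1))
        }
      }

      balls[[length(balls) + 1L]] <- ball
      ells[[length(ells) + 1L]] <- ell
      rhos[[length(rhos) + 1L]] <- rho
      centers_k[[length(centers_k) + 1L]] <- lin$k0_design
      stats_[[length(stats_) + 1L]] <-
        list(median = stats::median(errs, na.rm = TRUE),
             max = suppressWarnings(max(errs, na.rm = TRUE)),
             n = sum(!is.na(errs)), errors = errs)

      covered <- covered | in_ball(ball, mc_pts)
      cov_path <- c(cov_path, mean(covered))
      sm_log("INFO", "ball %d: delta %.4g, coverage %.4f",
             length(balls), delta, mean(covered))

      if (mean(covered) >= coverage_target) break
      if (all(covered)) break
      walk <- ball
    }

    p <- mean(covered)
    structure(list(balls = balls, ellipsoids = ells, rho = rhos,
                   centers_k = centers_k,
                   error_stats = stats_,
                   coverage_fraction = p,
                   coverage_se = sqrt(p * (1 - p) / n_mc),
                   coverage_path = cov_path,
                   n_mc = n_mc, seed = seed, eps = eps,
                   n_balls = length(balls), max_balls = max_balls,
                   complete = p >= coverage_target,
                   region = region),
              class = "coverage_result")
  })
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<coverage_result> %d balls, coverage %.4f (MC se %.4f, n = %g), ",
    "eps = %g%s\n"),
    x$n_balls, x$coverage_fraction, x$coverage_se, x$n_mc, x$eps,
    if (x$complete) "" else " [budget exhausted before target]"))
  if (x$n_balls) {
    radii <- vapply(x$balls, `[[`, numeric(1), "radius")
    cat(sprintf("  ball radii: min %.4g / median %.4g / max %.4g\n",
                min(radii), stats::median(radii), max(radii)))
  }
  invisible(x)
}
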