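random_matrix <- function(m, p, rank_deficient = FALSE) {
  if (rank_deficient && min(m, p) > 1) {
    r <- sample(seq_len(min(m, p) - 1), 1)
    matrix(stats::rnorm(m * r), m, r) %*% matrix(stats::rnorm(r * p), r, p)
  } else {
    matrix(stats::rnorm(m * p), m, p)
  }
}

mp_residuals <- function(L, Ldag) {
  c(max(abs(L %*% Ldag %*% L - L)),
    max(abs(Ldag %*% L %*% Ldag - Ldag)),
    max(abs(L %*% Ldag - t(L %*% Ldag))),
    max(abs(Ldag %*% L - t(Ldag %*% L))))
}

test_that("pseudoinverse handles the canonical small cases", {
  expect_equal(pseudo_inverse(diag(2))$Ldag, diag(2))
  # wide 1x2 row: minimum-norm inverse splits the weight
  expect_equal(pseudo_inverse(matrix(c(1, 1), 1, 2))$Ldag,
               matrix(0.5, 2, 1), tolerance = 1e-14)
  # rank-deficient diagonal: zero block stays zero
  pi3 <- pseudo_inverse(diag(c(3, 0)))
  expect_equal(pi3$Ldag, diag(c(1 / 3, 0)), tolerance = 1e-14)
  expect_identical(pi3$rank, 1L)
  # all-zero matrix allowed
  expect_equal(pseudo_inverse(matrix(0, 2, 3))$Ldag, matrix(0, 3, 2))
})

test_that("pseudoinverse satisfies the Moore-Penrose axioms", {
  set.seed(1)
  for (rep in 1:40) {
    L <- random_matrix(sample(1:6, 1), sample(1:6, 1),
                       rank_deficient = rep %% 3 == 0)
    res <- mp_residuals(L, pseudo_inverse(L)$Ldag)
    expect_lt(max(res), 1e-10 * max(1, max(abs(L))))
  }
})

test_that("SVD pseudoinverse is the limit of the ridge-regularized form", {
  # full-rank matrix with known singular values: the ridge error is ~lambda
  # all the way down
  set.seed(2)
  Q1 <- qr.Q(qr(random_matrix(4, 4)))[, 1:2]
  Q2 <- qr.Q(qr(random_matrix(2, 2)))
  L <- Q1 %*% diag(c(2, 1)) %*% t(Q2)
  Ldag <- pseudo_inverse(L)$Ldag
  errs <- sapply(10^seq(-2, -12, by = -2), function(lam)
    max(abs(pinv_limit(L, lam) - Ldag)))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[length(errs)], 1e-10)
  # a numerically rank-deficient matrix converges down to the noise floor
  # of its spurious singular value (~1e-16), so sweep only to 1e-6
  Lr <- random_matrix(4, 3, rank_deficient = TRUE)
  Ldr <- pseudo_inverse(Lr)$Ldag
  errs_r <- sapply(10^seq(-2, -6), function(lam)
    max(abs(pinv_limit(Lr, lam) - Ldr)))
  expect_true(all(diff(errs_r) < 0))
  expect_lt(errs_r[length(errs_r)], 1e-5)
})

test_that("feature balls map to parameter ellipsoids with exact axes", {
  # identity map: the ellipsoid is the ball itself
  ell <- map_ball(pseudo_inverse(diag(2)), feature_ball(c(0, 0), 0.3),
                  c(1, 1))
  expect_equal(ell$semi_axes, c(0.3, 0.3))
  expect_true(in_ellipsoid(ell, c(1.29, 1)))
  expect_false(in_ellipsoid(ell, c(1.31, 1)))

  # diagonal map L = diag(0.5, 2): Ldag = diag(2, 0.5), semi-axes delta*(1/s)
  pinv <- pseudo_inverse(diag(c(0.5, 2)))
  ell <- map_ball(pinv, feature_ball(c(0, 0), 1), c(0, 0))
  expect_equal(sort(ell$semi_axes), c(0.5, 2))
  # boundary points of the ball land on the ellipsoid boundary
  theta <- seq(0, 2 * pi, length.out = 33)
  B <- rbind(cos(theta), sin(theta))
  K <- t(pinv$Ldag %*% B)
  z <- t(ell$axes) %*% (t(K) - ell$center)
  keep <- ell$pinv$d > ell$pinv$cutoff
  r <- sqrt(colSums((z[keep, ] * ell$pinv$d[keep])^2))
  expect_equal(r, rep(1, 33), tolerance = 1e-10)

  # degenerate radius: ellipsoid collapses to the center
  ell0 <- map_ball(pseudo_inverse(diag(2)), feature_ball(c(0, 0), 0), c(2, 3))
  expect_equal(ell0$semi_axes, c(0, 0))
  expect_equal(as.numeric(sample_ellipsoid(ell0, 1, seed = 1)), c(2, 3))
})

test_that("ellipsoid sampling is inside, seeded, and rejects negatives", {
  pinv <- pseudo_inverse(matrix(c(2, 0.3, -0.5, 1), 2, 2))
  ell <- map_ball(pinv, feature_ball(c(5, 7), 0.8), c(2, 3))
  s1 <- sample_ellipsoid(ell, 50, seed = 99)
  s2 <- sample_ellipsoid(ell, 50, seed = 99)
  expect_identical(unclass(s1)[, ], unclass(s2)[, ])
  expect_true(all(in_ellipsoid(ell, s1)))
  fs <- attr(s1, "features")
  expect_true(all(sqrt(colSums((t(fs) - c(5, 7))^2)) <= 0.8 + 1e-12))

  # an ellipsoid entirely outside the positive orthant cannot be sampled
  tight <- map_ball(pseudo_inverse(diag(2)), feature_ball(c(0, 0), 1),
                    c(-5, -5))
  expect_error(sample_ellipsoid(tight, 20, seed = 1), "positive")
  # mild case: some rejections, all survivors nonnegative
  mild <- map_ball(pseudo_inverse(diag(2)), feature_ball(c(0, 0), 1),
                   c(0.5, 0.5))
  s3 <- sample_ellipsoid(mild, 100, seed = 4)
  expect_true(all(s3 >= 0))
  expect_gt(attr(s3, "n_rejected"), 0)
})

test_that("secant updates interpolate the sampled point exactly", {
  # hand-checkable instance
  Lt <- rank_one_update(diag(2), k0 = c(0, 0), f0 = c(0, 0),
                        ki = c(1, 0), Fki = c(2, 0))
  expect_equal(Lt, matrix(c(2, 0, 0, 1), 2, 2))
  # consistency property on random instances
  set.seed(6)
  for (rep in 1:30) {
    m <- sample(1:4, 1); p <- sample(1:4, 1)
    L <- random_matrix(m, p)
    k0 <- stats::rnorm(p); ki <- k0 + stats::rnorm(p)
    f0 <- stats::rnorm(m); Fki <- stats::rnorm(m)
    Lt <- rank_one_update(L, k0, f0, ki, Fki)
    expect_lt(max(abs(Lt %*% (ki - k0) - (Fki - f0))), 1e-12 * max(1, max(abs(Fki))))
    # zero residual: update leaves L untouched
    Lt2 <- rank_one_update(L, k0, f0, ki, f0 + L %*% (ki - k0))
    expect_equal(Lt2, L, tolerance = 1e-12)
  }
  expect_error(rank_one_update(diag(2), c(1, 1), c(0, 0), c(1, 1), c(1, 1)),
               "degenerate")
})

test_that("rho vanishes for linear maps and tracks known curvature", {
  # exactly linear forward map: all secant updates equal L
  net <- linear_source_network()
  sub <- design_subset(net, c("k1", "k2"))
  setup <- simulation_setup(c(0, 0), 1, n_grid = 40)
  kern <- integral_kernel(1, 2)
  lin <- linearize(net, kern, setup = setup, subset = sub)
  rho <- estimate_rho(net, kern, lin, c(0.05, 0.1, 0.2), n_samples = 5,
                      seed = 8, setup = setup, subset = sub)
  expect_lt(max(rho$rho_values), 1e-7)

  # F(k) = k^2/2 at k0 = 1: ||Ltilde - L|| = |dk|/2 with |dk| <= delta
  qnet <- quadratic_network()
  qsub <- design_subset(qnet, "k")
  qsetup <- simulation_setup(0, 1, n_grid = 40)
  qlin <- linearize(qnet, integral_kernel(1, 1), setup = qsetup,
                    subset = qsub)
  expect_equal(as.numeric(qlin$L), 1, tolerance = 1e-7)
  delta <- 0.3
  qrho <- estimate_rho(qnet, integral_kernel(1, 1), qlin, delta,
                       n_samples = 200, seed = 9, setup = qsetup,
                       subset = qsub)
  expect_lt(qrho$rho_values, delta / 2 * 1.001)
  expect_gt(qrho$rho_values, delta / 2 * 0.9)

  # running max keeps rho nondecreasing on the sensor
  o <- cs_objects()
  lin <- cs_linmap()
  srho <- estimate_rho(o$net, o$kernel, lin, c(50, 150, 400), n_samples = 4,
                       seed = 10, setup = o$setup, input = o$inp,
                       subset = o$subset)
  expect_true(all(diff(srho$rho_values) >= 0))
  expect_true(all(srho$rho_values >= 0))
})

test_that("maximal ball radius solves the error-bound program", {
  pinv <- pseudo_inverse(diag(c(2, 0.5))) # sigma_max(Ldag) = 2
  fake_rho <- function(grid, vals)
    structure(list(delta_grid = grid, rho_values = vals, n_samples = 1,
                   seed = 1, n_failed = 0), class = "rho_estimate")
  # rho == 0: unconstrained, radius hits the cap
  expect_equal(max_ball_radius(fake_rho(c(1, 2), c(0, 0)), pinv,
                               eps = 0.1, delta_cap = 7), 7)
  # constant rho = c: delta* = eps / (c * sigma_max)
  rho_c <- fake_rho(c(1e-9, 10), c(0.5, 0.5))
  expect_equal(max_ball_radius(rho_c, pinv, eps = 3, delta_cap = 10),
               3 / (0.5 * 2), tolerance = 1e-9)
  expect_equal(max_ball_radius(rho_c, pinv, eps = 1e6, delta_cap = 10), 10)
  # eps = 0 with curvature: degenerate zero radius, with a warning
  expect_warning(
    d0 <- max_ball_radius(fake_rho(c(1, 2), c(0.1, 0.2)), pinv, 0, 5),
    "radius is 0")
  expect_equal(d0, 0)
})

test_that("reverse-forward error vanishes where the map is linear", {
  net <- linear_source_network()
  sub <- design_subset(net, c("k1", "k2"))
  setup <- simulation_setup(c(0, 0), 1, n_grid = 40)
  kern <- integral_kernel(1, 2)
  lin <- linearize(net, kern, setup = setup, subset = sub)
  pinv <- pseudo_inverse(lin$L)
  expect_lt(reverse_forward_error(net, kern, lin, pinv, lin$f0, setup,
                                  subset = sub), 1e-9)
  expect_lt(reverse_forward_error(net, kern, lin, pinv, c(0.9, 0.2), setup,
                                  subset = sub), 1e-7)
  # negative back-mapped rates: reject or clamp per configuration
  f_neg <- c(-2, 0.5)
  r <- reverse_forward_error(net, kern, lin, pinv, f_neg, setup,
                             subset = sub)
  expect_true(is.na(r))
  expect_true(attr(r, "rejected"))
  rc <- reverse_forward_error(net, kern, lin, pinv, f_neg, setup,
                              subset = sub, negative = "clamp")
  expect_true(is.finite(rc))
  expect_true(attr(rc, "clamped"))
})
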