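test_that("the empirical effective potential of a Gaussian is quadratic", {
  set.seed(91)
  x <- rnorm(1e5)
  eff <- empirical_effective_potential(x, n_bins = 40)
  keep <- abs(eff$phi) < 2
  resid <- eff$R[keep] - eff$phi[keep]^2 / 2
  resid <- resid - mean(resid)  # R is defined up to a constant
  expect_lt(sqrt(mean(resid^2)), 0.05)
  expect_error(empirical_effective_potential(rnorm(20)), ">= 50")
})

test_that("a bimodal sample yields a two-minimum landscape; empty bins are dropped", {
  set.seed(92)
  x <- c(rnorm(3000, 2, 0.3), rnorm(7000, 5.5, 0.4))
  eff <- empirical_effective_potential(x, n_bins = 40)
  expect_true(all(eff$count > 0))
  # the tails beyond the data can fit with a non-confining leading term;
  # that is warned about but does not spoil bistability on the support
  pot <- suppressWarnings(fit_polynomial_potential(eff, order = 6))
  expect_true(attr(pot, "bistable"))
  fp <- attr(pot, "fixed_points")
  expect_lt(abs(fp$C_L - 2), 0.3)
  expect_lt(abs(fp$C_H - 5.5), 0.3)
})

test_that("polynomial landscape fitting recovers known coefficients", {
  true_coef <- c(1, -0.5, 2.2, -0.9, -0.35, 0.08, 0.05)  # order 6, confining
  phi <- seq(-2, 3, length.out = 60)
  set.seed(93)
  eff <- tibble::tibble(phi = phi,
                        R = gutload::potential_value(
                          poly_potential(true_coef), phi) + rnorm(60, 0, 0.02),
                        count = rep(200L, 60))
  class(eff) <- c("effective_potential", class(eff))
  pot <- fit_polynomial_potential(eff, order = 6)
  pred <- potential_value(pot, phi)
  truth <- potential_value(poly_potential(true_coef), phi)
  expect_lt(max(abs(pred - truth)), 0.05)
  expect_error(fit_polynomial_potential(eff, order = 3), "even")
  expect_error(fit_polynomial_potential(eff, order = 2), "even and >= 4")
})

test_that("higher-order landscapes never fit worse than nested lower orders", {
  set.seed(94)
  x <- c(rnorm(3000, 2, 0.25), rnorm(7000, 5.5, 0.5))
  eff <- empirical_effective_potential(x, n_bins = 40)
  r4 <- attr(suppressWarnings(fit_polynomial_potential(eff, order = 4)), "residual")
  r6 <- attr(suppressWarnings(fit_polynomial_potential(eff, order = 6)), "residual")
  expect_lte(r6, r4)
})

test_that("fixed points and curvatures match closed forms and a grid oracle", {
  fp <- find_fixed_points(double_well(0.05), support = c(-3, 3))
  expect_equal(fp$C_L, -1); expect_equal(fp$C_M, 0); expect_equal(fp$C_H, 1)
  expect_equal(fp$K_L, 2); expect_equal(fp$K_M, 1); expect_equal(fp$K_H, 2)
  expect_error(find_fixed_points(poly_potential(c(0, 0, 0.5), D = 1),
                                 support = c(-3, 3)), "not bistable")
  # randomized bistable sextics vs a dense-grid argmin oracle
  set.seed(95)
  for (i in 1:10) {
    a <- sort(runif(3, -2, 2))
    if (min(diff(a)) < 0.3) next
    # U'(x) = (x - a1)(x - a2)(x - a3) integrated analytically
    e <- c(-a[1] - a[2] - a[3], a[1] * a[2] + a[1] * a[3] + a[2] * a[3],
           -prod(a))
    coef <- c(0, -prod(a), (a[1] * a[2] + a[1] * a[3] + a[2] * a[3]) / 2,
              -(a[1] + a[2] + a[3]) / 3, 1 / 4)
    pot <- poly_potential(coef, D = 0.05)
    fp2 <- find_fixed_points(pot, support = c(-4, 4))
    grid <- seq(-4, 4, length.out = 200001)
    u <- potential_value(pot, grid)
    left <- grid[grid < fp2$C_M]; right <- grid[grid > fp2$C_M]
    expect_lt(abs(fp2$C_L - left[which.min(u[grid < fp2$C_M])]), 1e-4)
    expect_lt(abs(fp2$C_H - right[which.min(u[grid > fp2$C_M])]), 1e-4)
  }
})

test_that("Kramers rates respect symmetry and barrier monotonicity", {
  pot <- double_well(0.05)
  fp <- find_fixed_points(pot, support = c(-2, 2))
  kr <- kramers_rates(pot, fp)
  expect_equal(kr$alpha_h, kr$alpha_l)
  # scaling the barrier up at fixed D lowers both rates
  kr2 <- kramers_rates(poly_potential(2 * pot$coefficients, D = 0.05),
                       support = c(-2, 2))
  expect_lt(kr2$alpha_h, kr$alpha_h)
  expect_lt(kr2$alpha_l, kr$alpha_l)
})

test_that("Kramers rates agree with first-passage simulation within a factor of 2", {
  pot <- double_well(0.0625)  # barrier/D = 4
  fp <- find_fixed_points(pot, support = c(-2, 2))
  kr <- kramers_rates(pot, fp)
  emp <- first_passage_rate(pot, from = fp$C_H, to = fp$C_L, n_runs = 200,
                            dt = 0.005, t_max = 1e4, seed = 96)
  expect_equal(emp$n_censored, 0)
  ratio <- emp$rate / kr$alpha_l
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})

test_that("noise estimation inverts the Kramers rate exactly", {
  pot <- double_well(0.06)
  fp <- find_fixed_points(pot, support = c(-2, 2))
  alpha_l <- kramers_rates(pot, fp)$alpha_l
  R <- poly_potential(pot$coefficients / pot$D, scale = "R")
  fpR <- find_fixed_points(R, support = c(-2, 2))
  est <- estimate_noise_D(R, fpR, alpha_l = alpha_l)
  expect_lt(abs(est$D - pot$D), 1e-8)
  expect_equal(est$coefficients, pot$coefficients, tolerance = 1e-10)
  # doubling the measured rate doubles the implied crossing rate
  est2 <- estimate_noise_D(R, fpR, alpha_l = 2 * alpha_l)
  expect_equal(est2$D / est$D, 2, tolerance = 1e-10)
  # zero-barrier limit: the exponential factor drops out
  fp_flat <- structure(list(C_L = -1, C_M = 0, C_H = 1,
                            K_L = 2, K_M = 1, K_H = 2), class = "fixed_points")
  Rflat <- poly_potential(c(0, 0, 0, 0, 1e-12), scale = "R")  # numerically flat
  estf <- estimate_noise_D(Rflat, fp_flat, alpha_l = 0.1)
  expect_equal(estf$D, 2 * pi * 0.1 / sqrt(2 * 1), tolerance = 1e-6)
})

test_that("the Boltzmann density normalizes and reduces to a Gaussian for quadratic wells", {
  # U = k (phi - mu)^2 / 2 -> Gaussian with variance D / k
  k <- 1.7; mu <- 1.2; D <- 0.3
  pot <- poly_potential(c(k * mu^2 / 2, -k * mu, k / 2), D = D)
  f <- potential_stationary_pdf(pot, support = mu + c(-6, 6))
  expect_equal(integrate(f, mu - 6, mu + 6, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  xs <- seq(mu - 2, mu + 2, by = 0.1)
  expect_equal(f(xs), dnorm(xs, mu, sqrt(D / k)), tolerance = 1e-4)
})

test_that("Langevin trajectories sample the Boltzmann density and basin weights", {
  pot <- double_well(0.0625)
  fp <- find_fixed_points(pot, support = c(-2, 2))
  tr <- simulate_potential(pot, phi0 = 1, t_end = 1e6, dt = 0.01, seed = 97,
                           record_every = 1000, support = c(-2, 2))
  xs <- tr$phi[tr$time_h > 200]
  f <- potential_stationary_pdf(pot, support = c(-2.5, 2.5))
  grid <- seq(-2.5, 2.5, length.out = 4001)
  dens <- f(grid)
  steps <- (dens[-1] + dens[-length(dens)]) / 2 * diff(grid)
  cdf <- c(0, cumsum(steps)) / sum(steps)
  ks <- max(abs(ecdf(xs)(grid) - cdf))
  expect_lt(ks, 0.05)
  # time in the high basin matches the Kramers occupancy
  kr <- kramers_rates(pot, fp)
  occ <- mean(xs > fp$C_M)
  p_star <- kr$alpha_h / (kr$alpha_h + kr$alpha_l)
  n_eff <- 1e6 * (kr$alpha_h + kr$alpha_l) / 2
  expect_lt(abs(occ - p_star), 3 * sqrt(p_star * (1 - p_star) / n_eff))
})

test_that("noiseless gradient descent converges and the blow-up guard trips", {
  pot <- double_well(1e-12)
  tr <- simulate_potential(pot, phi0 = 0.4, t_end = 50, dt = 0.01, seed = 1,
                           support = c(-2, 2))
  expect_equal(tr$phi[nrow(tr)], 1, tolerance = 1e-4)
  # halving dt barely moves the stationary variance (single confining well,
  # so the estimate is not dominated by rare basin hops)
  well <- poly_potential(c(0, 0, 0.5, 0, 0.25), D = 0.05)
  v1 <- var(simulate_potential(well, 0, 2e4, dt = 0.01, seed = 2,
                               record_every = 10, support = c(-3, 3))$phi)
  v2 <- var(simulate_potential(well, 0, 2e4, dt = 0.005, seed = 2,
                               record_every = 20, support = c(-3, 3))$phi)
  expect_lt(abs(v2 - v1) / v1, 0.03)
  # inverted (non-confining) potential escapes and trips the guard
  bad <- poly_potential(c(0, 0, -1), D = 0.01)
  expect_error(simulate_potential(bad, 0.1, 100, dt = 0.01, seed = 3,
                                  support = c(-1, 1)), "support")
})
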