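test_that("Gillespie trajectories respect absorbing and pure-death regimes", {
  # no source reactions
  tr <- gillespie_run(logistic_rates(1, 0, 0.2, 100), N0 = 0, t_end = 20, seed = 1)
  expect_equal(tr$counts, 0L)
  # pure death: monotone nonincreasing to extinction
  tr2 <- gillespie_run(logistic_rates(0, 0, 0.5, 100), N0 = 50, t_end = 200, seed = 2)
  expect_true(all(diff(tr2$counts) <= 0))
  expect_equal(tr2$counts[nrow(tr2)], 0L)
})

test_that("counts stay within [0, V] for randomized parameters", {
  set.seed(5)
  for (i in 1:15) {
    V <- sample(c(50, 200, 1000), 1)
    r <- logistic_rates(runif(1, 0, 2), runif(1, 0, 0.3), runif(1, 0, 1), V)
    tr <- gillespie_run(r, N0 = sample(0:V, 1), t_end = 10,
                        seed = sample.int(1e6, 1))
    expect_true(all(tr$counts >= 0 & tr$counts <= V))
    expect_true(all(diff(tr$event_times) >= 0))
  }
})

test_that("the ensemble mean tracks the mean-field ODE within 3 MC SE", {
  # times where the finite-V correction to the mean is below one MC SE
  r <- logistic_rates(1, 0.05, 0.2, 1000)
  tpts <- c(1, 2, 3, 24, 48)
  sim <- simulate_ensemble(r, n_worms = 300, times = tpts, seed = 11)
  stat <- dplyr::summarise(dplyr::group_by(sim, time_h),
                           m = mean(load), se = sd(load) / sqrt(dplyr::n()),
                           .groups = "drop")
  ode <- solve_meanfield(r, 0, tpts)
  expect_true(all(abs(stat$m - ode$phi * r$V) < 3 * stat$se))
})

test_that("across-worm variance at saturation is demographic, shrinking with V", {
  sat_relvar <- function(V) {
    r <- logistic_rates(1, 0.05, 0.2, V)
    sim <- simulate_ensemble(r, n_worms = 200, times = 60, seed = 21)
    var(sim$load) / mean(sim$load)^2
  }
  rv_small <- sat_relvar(100)
  rv_big <- sat_relvar(10000)
  expect_lt(rv_big, rv_small / 10)   # relative variance scales like 1/V
  expect_lt(rv_big, 0.01)            # variance << mean^2 at large V
})

test_that("capacity resampling yields a bimodal late-time load distribution", {
  r <- logistic_rates(1, 0.05, 0.1, 1000)
  het <- heterogeneity_spec(birth_mean = 1, colonization_mean = 0.05,
                            capacity_pool = c(100, 1e5))
  sim <- simulate_ensemble(r, het, n_worms = 60, times = 80, seed = 31)
  near <- function(x, target) abs(log10(x) - log10(target)) < 0.25
  sat <- 1 - r$d / 1  # occupancy fraction at saturation
  expect_gt(mean(near(sim$load, 100 * sat)), 0.2)
  expect_gt(mean(near(sim$load, 1e5 * sat)), 0.2)
  expect_gt(mean(near(sim$load, 100 * sat) | near(sim$load, 1e5 * sat)), 0.9)
})

test_that("uncolonized fractions fall stochastically with colonization rate", {
  times <- c(3, 6, 12)
  # colonization propensity is per empty site (c * E), so per-worm arrival
  # rates here are c * V = 0.01, 0.1, 1 per hour
  frac_zero <- vapply(c(1e-5, 1e-4, 1e-3), function(cc) {
    sim <- simulate_ensemble(logistic_rates(0.5, cc, 0.1, 1000),
                             n_worms = 200, times = times, seed = 77)
    mean(zero_occupancy(sim)$p_zero)
  }, numeric(1))
  expect_true(all(diff(frac_zero) < 0))
})

test_that("zero-occupancy fractions carry exact binomial standard deviations", {
  snap <- make_snapshot(12, c(rep(0, 6), rep(500, 18)))
  z <- zero_occupancy(snap)
  expect_equal(z$p_zero, 0.25)
  expect_equal(z$sd_zero, sqrt(24 * 0.25 * 0.75) / 24)
  expect_equal(z$pct_zero, 25)
  all0 <- zero_occupancy(make_snapshot(12, rep(0, 24)))
  expect_equal(all0$p_zero, 1); expect_equal(all0$sd_zero, 0)
  none0 <- zero_occupancy(make_snapshot(12, rep(10, 24)))
  expect_equal(none0$p_zero, 0); expect_equal(none0$sd_zero, 0)
})

test_that("load discretization uses boundary-to-lower-level ties and conserves counts", {
  thr <- c(10^1.5, 10^4)
  snap <- make_snapshot(c(12, 24), c(0, 10^1.5, 10^2, 10^5, 10^4, 10^6, 1, 3))
  lc <- discretize_loads(snap, thr)
  expect_s3_class(lc, "level_counts")
  # boundary 10^1.5 -> low; 10^4 -> medium; 10^5, 10^6 -> high
  at <- function(t, lvl) lc$n[lc$time_h == t & lc$level == lvl]
  expect_equal(at(12, "low"), 2L)    # 0 and 10^1.5
  expect_equal(at(12, "medium"), 1L) # 10^2
  expect_equal(at(12, "high"), 1L)   # 10^5
  # counts conserved per time
  tot <- dplyr::summarise(dplyr::group_by(lc, time_h), n = sum(n))
  expect_equal(tot$n, c(4L, 4L))
  # empty snapshot -> all-zero counts
  empty <- discretize_loads(make_snapshot(numeric(), numeric(), 0), thr)
  expect_equal(nrow(empty), 0L)
})

test_that("the discretized negative log-likelihood matches hand arithmetic", {
  snap <- make_snapshot(12, c(rep(1, 8), rep(100, 8), rep(1e5, 8)))
  obs <- discretize_loads(snap, c(10^1.5, 10^4))
  unif <- tibble::tibble(time_h = 12, level = c("low", "medium", "high"),
                         p = rep(1 / 3, 3))
  expect_equal(negative_log_likelihood(obs, unif), 24 * log(3))
  # Gibbs inequality: the empirical frequencies minimize the NLL
  emp <- tibble::tibble(time_h = 12, level = c("low", "medium", "high"),
                        p = c(8, 8, 8) / 24)
  skew <- tibble::tibble(time_h = 12, level = c("low", "medium", "high"),
                         p = c(0.6, 0.3, 0.1))
  expect_lt(negative_log_likelihood(obs, emp),
            negative_log_likelihood(obs, skew))
  # zero counts contribute zero
  none <- discretize_loads(make_snapshot(numeric(), numeric(), 0), c(1, 10))
  expect_equal(negative_log_likelihood(none, unif), 0)
})

test_that("grid search recovers the generating heterogeneity point", {
  V <- 10000
  rates <- logistic_rates(b = 0.4, c = 0.005, d = 0.1, V = V)
  times <- c(3, 12, 24, 36, 48)
  truth <- heterogeneity_spec(birth_mean = 0.4, birth_sd = 0.1,
                              colonization_mean = 0.005,
                              colonization_sd = 0.002)
  snap <- simulate_ensemble(rates, truth, n_worms = 24, times = times,
                            seed = 100)
  grid <- tidyr::crossing(birth_mean = c(0.2, 0.4, 0.6),
                          colonization_mean = c(0.001, 0.005, 0.02))
  grid$birth_sd <- 0.1; grid$colonization_sd <- 0.002
  gs <- grid_search_heterogeneous(snap, grid, rates,
                                  thresholds = c(10^1.5, 10^3.5),
                                  n_worms_sim = 120, n_rep = 30, seed = 101)
  expect_equal(gs$best$birth_mean, 0.4)
  expect_equal(gs$best$colonization_mean, 0.005)
  expect_false(gs$rejected)
  expect_length(gs$nll_sim, 30)
})

test_that("a single grid point is returned as best trivially", {
  rates <- fix_rates()
  snap <- simulate_ensemble(rates, n_worms = 12, times = c(12, 24), seed = 5)
  gs <- grid_search_heterogeneous(
    snap, data.frame(birth_mean = 0.4), rates,
    thresholds = c(10, 500), n_worms_sim = 24, n_rep = 5, seed = 6)
  expect_equal(gs$best$birth_mean, 0.4)
})

test_that("badly misspecified data are flagged as rejected", {
  rates <- logistic_rates(b = 0.4, c = 0.005, d = 0.1, V = 10000)
  times <- c(3, 12, 24, 36, 48)
  # data from a hugely heterogeneous capacity pool, fit by a homogeneous model
  het <- heterogeneity_spec(birth_mean = 0.4, colonization_mean = 0.05,
                            capacity_pool = c(30, 10000))
  snap <- simulate_ensemble(rates, het, n_worms = 24, times = times, seed = 9)
  gs <- grid_search_heterogeneous(
    snap, data.frame(birth_mean = 0.4, colonization_mean = 0.005), rates,
    thresholds = c(10^1.5, 10^3.5), n_worms_sim = 240, n_rep = 40, seed = 10)
  expect_true(gs$rejected)
})
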