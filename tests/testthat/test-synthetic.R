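test_that("destructive CFU snapshots have the published design shape", {
  snap <- gen_logistic_snapshot(fix_rates(), n_worms = 24,
                                times = fix_times(), seed = 1)
  expect_equal(nrow(snap), 24 * 7)
  # independent worms at each time point
  per_time <- dplyr::count(snap, time_h)
  expect_true(all(per_time$n == 24))
  ids <- dplyr::distinct(snap, worm_id, time_h)
  expect_equal(nrow(ids), nrow(snap))  # one record per worm
  expect_true(all(snap$modality == "cfu"))
  # empty and deterministic cases
  expect_equal(nrow(gen_logistic_snapshot(fix_rates(), n_worms = 0,
                                          times = fix_times())), 0)
  again <- gen_logistic_snapshot(fix_rates(), n_worms = 24,
                                 times = fix_times(), seed = 1)
  expect_identical(snap, again)
})

test_that("switching populations are longitudinal with recorded true states", {
  model <- fix_switching()
  pop <- gen_switching_population(model, n_worms = 150, times = c(0, 24, 48),
                                  p0_high = 0, seed = 2)
  expect_equal(nrow(pop), 150 * 3)
  expect_equal(dplyr::n_distinct(pop$worm_id), 150)
  # fraction high rises toward the stationary occupancy
  frac <- dplyr::summarise(dplyr::group_by(pop, time_h),
                           p = mean(true_state == "high"))
  expect_equal(frac$p[1], 0)
  expect_true(all(diff(frac$p) > 0))
  theory <- occupancy_solution(model$alpha_h, model$alpha_l, 0, c(24, 48))
  expect_lt(max(abs(frac$p[2:3] - theory$p_high)), 0.12)
  # frozen states without switching
  frozen <- gen_switching_population(
    switching_model(1, 2, 0.2, 1, 5.5, 0.2, alpha_h = 0, alpha_l = 0.001),
    n_worms = 30, times = c(0, 24, 48), p0_high = 0, seed = 3)
  expect_true(all(frozen$true_state == "low"))
})

test_that("the measurement model floors, saturates, and stays monotone", {
  mm <- measurement_model(background_sd = 0.05)
  # zero load -> pure background draw
  snap0 <- make_snapshot(0, rep(0, 200))
  gfp0 <- apply_measurement(snap0, mm, seed = 4)
  expect_equal(mean(gfp0$loggfp), mm$background_level, tolerance = 0.02)
  expect_true(all(gfp0$modality == "gfp"))
  # ceiling effect: 10^8 CFU reads within 2% of the asymptote, 10^10 within 1%
  # (tanh((8 - 0.884)/3.064) = 0.981, so 1% is only reached near 10^9.4)
  gfp_hi <- apply_measurement(make_snapshot(0, rep(1e8, 50)), mm, seed = 5)
  expect_true(all(abs(gfp_hi$loggfp - mm$calibration$a) / mm$calibration$a < 0.02))
  gfp_hi10 <- apply_measurement(make_snapshot(0, rep(1e10, 50)), mm, seed = 5)
  expect_true(all(abs(gfp_hi10$loggfp - mm$calibration$a) / mm$calibration$a < 0.01))
  # median GFP nondecreasing across a load ladder
  ladder <- 10^(2:7)
  med <- vapply(ladder, function(L) {
    g <- apply_measurement(make_snapshot(0, rep(L, 500)), mm, seed = 6)
    median(g$loggfp)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("measured loads invert to true loads in the calibrated linear regime", {
  mm <- measurement_model(background_sd = 0.05)
  true_logs <- seq(3, 5, by = 0.25)
  snap <- make_snapshot(0, 10^true_logs)
  gfp <- apply_measurement(snap, mm, seed = 7)
  rec <- loggfp_to_logcfu(gfp$loggfp, mm$calibration)
  expect_lt(max(abs(rec - true_logs)), 0.1)
})

test_that("ground-truth columns survive a round trip through snapshot files", {
  snap <- gen_logistic_snapshot(fix_rates(), n_worms = 6, times = c(12, 24),
                                seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_snapshot(snap, path)
  back <- read_snapshot(path)
  expect_equal(back$true_b, snap$true_b)
  expect_equal(back$true_V, snap$true_V)
  expect_equal(back$load, snap$load)
})

test_that("sorter binning partitions worms and rejects overlapping gates", {
  model <- fix_switching()
  # measure at 24 h so within-state spread populates both sorter gates
  pop <- gen_switching_population(model, n_worms = 300, times = 24,
                                  p0_high = 0.5, seed = 9)
  gfp <- apply_measurement(pop, measurement_model(), seed = 10)
  bins <- gen_sorted_bins(gfp, low_range = c(45, 620), high_range = c(850, 3950))
  expect_true(all(bins$low$load >= 45 & bins$low$load <= 620))
  expect_true(all(bins$high$load >= 850 & bins$high$load <= 3950))
  expect_length(intersect(bins$low$worm_id, bins$high$worm_id), 0)
  expect_gt(nrow(bins$low), 0); expect_gt(nrow(bins$high), 0)
  expect_error(gen_sorted_bins(gfp, c(45, 900), c(850, 3950)), "disjoint")
  # all worms in the gap -> both bins empty
  gap <- make_snapshot(0, rep(700, 10))
  empty <- gen_sorted_bins(gap, c(45, 620), c(850, 3950))
  expect_equal(nrow(empty$low) + nrow(empty$high), 0)
})

test_that("sorted bins develop the opposite mode after switching evolution", {
  model <- fix_switching()
  pop <- gen_switching_population(model, n_worms = 300, times = 24,
                                  p0_high = 0.5, seed = 11)
  gfp0 <- apply_measurement(pop, measurement_model(background_sd = 0.05),
                            seed = 12)
  bins <- gen_sorted_bins(gfp0)
  evolve <- function(bin, s_col) {
    later <- gen_switching_population(
      model, n_worms = nrow(bin), times = c(0, 48),
      p0_high = mean(bin[[s_col]] == "high"), seed = 13)
    later[later$time_h == 48, ]
  }
  hi48 <- evolve(bins$high, "true_state")
  lo48 <- evolve(bins$low, "true_state")
  # each bin now contains both states
  expect_gt(mean(hi48$true_state == "low"), 0.05)
  expect_gt(mean(lo48$true_state == "high"), 0.3)
})
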