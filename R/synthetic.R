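#' Fluorescence measurement model
#'
#' Maps true bacterial loads to sorter fluorescence readings: loads below the
#' autofluorescence floor are reported as pure background; above it, the
#' calibration map of log10 load is combined with a background draw by
#' taking the larger of the two (autofluorescence masks weak signal), so the
#' output is bounded above by the calibration asymptote and below by worm
#' autofluorescence.
#'
#' @param calibration A [calibration_map()]; defaults to the fitted
#'   constants a = 4.00, b = 0.884, c = 3.064.
#' @param autofluorescence_floor Load (cells) below which only background is
#'   reported; the assay detection threshold is roughly 100 CFU per worm.
#' @param background_level Mean log10 GFP of uncolonized worms. The default
#'   (1.4) is the calibration map evaluated at the detection threshold; real
#'   autofluorescence distributions are not published, so this is a
#'   synthetic fixture choice.
#' @param background_sd Sd of log10 background fluorescence (> 0).
#' @return An object of class `measurement_model`.
#' @export
measurement_model <- function(calibration = calibration_map(4.00, 0.884, 3.064),
                              autofluorescence_floor = 100,
                              background_level = 1.4,
                              background_sd = 0.2) {
  stopifnot(inherits(calibration, "calibration_map"))
  assert_number(autofluorescence_floor, "autofluorescence_floor", lower = 0)
  assert_number(background_level, "background_level")
  assert_number(background_sd, "background_sd")
  if (background_sd <= 0) abort("`background_sd` must be positive")
  structure(list(calibration = calibration,
                 autofluorescence_floor = autofluorescence_floor,
                 background_level = background_level,
                 background_sd = background_sd),
            class = "measurement_model")
}

#' Generate a destructive-sampling CFU snapshot
#'
#' Wraps [simulate_ensemble()] with destructive-sampling semantics: an
#' independent cohort of worms is simulated for each time point, matching
#' the single-worm digest design in which each worm yields one CFU count.
#' Ground-truth per-worm parameters are kept as extra columns.
#'
#' @inheritParams simulate_ensemble
#' @return A snapshot tibble (`worm_id`, `time_h`, `load`, `condition`,
#'   `modality = "cfu"`, plus `true_b`, `true_c`, `true_V`); worm ids are
#'   unique within each time point.
#' @examples
#' gen_logistic_snapshot(logistic_rates(1, 0.05, 0.2, 500), n_worms = 4,
#'                       times = c(12, 24), seed = 1)
#' @export
gen_logistic_snapshot <- function(rates, het = NULL, n_worms, times,
                                  seed = NULL, condition = "sim") {
  if (n_worms == 0) {
    out <- simulate_ensemble(rates, het, 0, times = times %||% 1,
                             condition = condition)
    out$modality <- character()
    return(out)
  }
  times <- sort(unique(as.numeric(times)))
  seeds <- derive_seeds(seed, length(times))
  rows <- purrr::map(seq_along(times), function(j) {
    cohort <- simulate_ensemble(rates, het, n_worms, times = times[j],
                                seed = seeds[j], condition = condition)
    cohort$worm_id <- sprintf("t%g_%s", times[j], cohort$worm_id)
    cohort
  })
  out <- dplyr::bind_rows(rows)
  out$modality <- "cfu"
  out
}

#' Generate a longitudinal switching population
#'
#' Simulates `n_worms` hosts under the two-state switching model and records
#' each worm's log-load and true state at the requested times (the same
#' worms across times, as in repeated fluorescence measurement). Loads are
#' reported as CFU (10^phi).
#'
#' @param model A [switching_model()].
#' @param n_worms Number of hosts.
#' @param times Observation times (hours, increasing).
#' @param p0_high Probability that a worm starts in the high state.
#' @param phi0_low,phi0_high Initial log10 loads per starting state;
#'   default to the state carrying capacities.
#' @param dt Euler-Maruyama step.
#' @param seed Seed.
#' @param condition Condition label.
#' @return Snapshot tibble with `worm_id`, `time_h`, `load`, `condition`,
#'   `modality = "cfu"` and ground-truth `true_state`.
#' @export
gen_switching_population <- function(model, n_worms, times, p0_high = 0,
                                     phi0_low = NULL, phi0_high = NULL,
                                     dt = 0.01, seed = NULL,
                                     condition = "sim") {
  stopifnot(inherits(model, "switching_model"))
  if (length(times) < 1 || any(diff(times) < 0)) abort("`times` must be increasing")
  times <- as.numeric(times)
  phi0_low <- phi0_low %||% model$C_low
  phi0_high <- phi0_high %||% model$C_high
  seeds <- derive_seeds(seed, n_worms + 1)
  set.seed(seeds[n_worms + 1])
  start_high <- runif(n_worms) < p0_high
  t_end <- max(times)
  rows <- purrr::map(seq_len(n_worms), function(i) {
    if (t_end == 0) {
      phi <- if (start_high[i]) phi0_high else phi0_low
      return(tibble(worm_id = sprintf("w%03d", i), time_h = times,
                    load = 10^phi,
                    condition = condition, modality = "cfu",
                    true_state = if (start_high[i]) "high" else "low"))
    }
    traj <- simulate_switching(
      model, phi0 = if (start_high[i]) phi0_high else phi0_low,
      s0 = if (start_high[i]) "high" else "low",
      t_end = t_end, dt = dt, seed = seeds[i]
    )
    idx <- vapply(times, function(tt) which.min(abs(traj$time_h - tt)),
                  integer(1))
    tibble(worm_id = sprintf("w%03d", i), time_h = times,
           load = 10^traj$phi[idx], condition = condition, modality = "cfu",
           true_state = traj$state[idx])
  })
  dplyr::bind_rows(rows)
}

#' Apply the fluorescence measurement model to a CFU snapshot
#'
#' Converts true loads to GFP readings (arbitrary units): records below the
#' autofluorescence floor become pure background draws; others are mapped
#' through the calibration and masked by background (the maximum of mapped
#' signal and a background draw, in log10 GFP). The raw fluorescence is
#' `10^loggfp`.
#'
#' @param snapshot A CFU snapshot (modality `"cfu"` if present).
#' @param mm A [measurement_model()].
#' @param seed Seed for the background draws.
#' @return The snapshot with `load` replaced by raw GFP, `loggfp` added, and
#'   `modality = "gfp"`; the true load is preserved in `true_load`.
#' @export
apply_measurement <- function(snapshot, mm = measurement_model(), seed = NULL) {
  assert_snapshot(snapshot)
  stopifnot(inherits(mm, "measurement_model"))
  if (!is.null(snapshot[["modality"]]) && any(snapshot[["modality"]] != "cfu")) {
    abort("`snapshot` must be in CFU modality")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(snapshot)
  background <- rnorm(n, mm$background_level, mm$background_sd)
  loggfp <- background
  above <- snapshot$load >= mm$autofluorescence_floor & snapshot$load > 0
  if (any(above)) {
    signal <- logcfu_to_loggfp(log10(snapshot$load[above]), mm$calibration)
    loggfp[above] <- pmax(signal, background[above])
  }
  out <- snapshot
  out$true_load <- snapshot$load
  out$load <- 10^loggfp
  out$loggfp <- loggfp
  out$modality <- "gfp"
  out
}

#' Partition a fluorescence snapshot into sorter bins
#'
#' Emulates the sorting experiment: worms whose raw GFP falls in `low_range`
#' go to the low bin, those in `high_range` to the high bin, and worms in
#' the gap between the (disjoint) ranges are discarded.
#'
#' @param snapshot A GFP snapshot (raw fluorescence in `load`).
#' @param low_range,high_range Length-2 numeric GFP ranges, disjoint with a
#'   gap; the published gates were roughly 45-620 (low) and 850-3950 (high).
#' @return A list with snapshot tibbles `low` and `high`.
#' @export
gen_sorted_bins <- function(snapshot, low_range = c(45, 620),
                            high_range = c(850, 3950)) {
  assert_snapshot(snapshot)
  low_range <- sort(low_range)
  high_range <- sort(high_range)
  if (low_range[2] >= high_range[1]) {
    abort("`low_range` and `high_range` must be disjoint with a gap")
  }
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  list(
    low = dplyr::filter(snapshot, in_range(.data$load, low_range)),
    high = dplyr::filter(snapshot, in_range(.data$load, high_range))
  )
}
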