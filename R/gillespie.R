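#' Exact stochastic simulation of gut colonization
#'
#' Runs the Gillespie algorithm for the colonization/birth/death reactions:
#' colonization of empty sites at propensity `c (V - N)`, birth into empty
#' sites at `b N (V - N) / V`, and death at `d N`. The birth propensity is
#' scaled by the empty-site fraction so that the large-V limit is exactly the
#' mean-field occupancy ODE.
#'
#' @param rates A [logistic_rates()] object.
#' @param N0 Initial bacterial count, `0 <= N0 <= V`.
#' @param t_end End time, hours.
#' @param seed Integer seed for reproducibility (optional).
#' @param max_events Event cap guarding against runaway trajectories.
#' @return A tibble of class `gillespie_trajectory` with columns
#'   `event_times` (hours, nondecreasing) and `counts` (N after each event;
#'   the first row is the initial condition), plus a `capacity` attribute.
#' @examples
#' gillespie_run(logistic_rates(1, 0.05, 0.2, 200), N0 = 0, t_end = 24, seed = 1)
#' @export
gillespie_run <- function(rates, N0, t_end, seed = NULL, max_events = 1e7) {
  stopifnot(inherits(rates, "logistic_rates"))
  assert_number(N0, "N0", lower = 0, upper = rates$V)
  assert_number(t_end, "t_end", lower = 0)
  res <- with_seed(seed, gillespie_events_cpp(
    rates$b, rates$c, rates$d, rates$V, as.integer(N0), t_end, max_events
  ))
  out <- tibble(event_times = res$event_times, counts = res$counts)
  attr(out, "capacity") <- rates$V
  class(out) <- c("gillespie_trajectory", class(out))
  out
}

#' Host-to-host parameter heterogeneity specification
#'
#' Describes stationary heterogeneity across hosts: per-worm birth and
#' colonization rates drawn from (zero-truncated) normal distributions, and
#' optionally per-worm carrying capacities resampled with replacement from an
#' empirical pool (e.g. late-time loads of the highest-inoculum condition).
#'
#' @param birth_mean,birth_sd Mean and sd of the per-worm birth rate (1/h).
#' @param colonization_mean,colonization_sd Mean and sd of the per-worm
#'   colonization rate (1/h).
#' @param capacity_pool Optional vector of carrying capacities (cells, >= 1)
#'   to resample with replacement.
#' @return An object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(birth_mean, birth_sd = 0,
                               colonization_mean, colonization_sd = 0,
                               capacity_pool = NULL) {
  assert_number(birth_mean, "birth_mean", lower = 0)
  assert_number(birth_sd, "birth_sd", lower = 0)
  assert_number(colonization_mean, "colonization_mean", lower = 0)
  assert_number(colonization_sd, "colonization_sd", lower = 0)
  if (!is.null(capacity_pool)) {
    if (length(capacity_pool) < 1 || any(capacity_pool < 1)) {
      abort("`capacity_pool` entries must be >= 1 cell")
    }
  }
  structure(list(birth_mean = birth_mean, birth_sd = birth_sd,
                 colonization_mean = colonization_mean,
                 colonization_sd = colonization_sd,
                 capacity_pool = capacity_pool),
            class = "heterogeneity_spec")
}

#' Simulate an ensemble of hosts
#'
#' Each worm receives independent parameter draws (zero-truncated normal
#' birth and colonization rates, and a capacity resampled from
#' `het$capacity_pool` when given), then one Gillespie trajectory sampled at
#' the requested times. Worms are followed longitudinally; see
#' [gen_logistic_snapshot()] for the destructive-sampling design used in CFU
#' experiments.
#'
#' @inheritParams gillespie_run
#' @param het Optional [heterogeneity_spec()]. When given, its means replace
#'   `rates$b` and `rates$c`.
#' @param n_worms Number of hosts (>= 1; 0 returns an empty snapshot).
#' @param times Sampling times in hours.
#' @param condition Condition label recorded in the output.
#' @param N0 Initial count per worm.
#' @return A snapshot tibble with columns `worm_id`, `time_h`, `load`,
#'   `condition`, plus per-worm ground-truth columns `true_b`, `true_c`,
#'   `true_V`.
#' @export
simulate_ensemble <- function(rates, het = NULL, n_worms, times, seed = NULL,
                              condition = "sim", N0 = 0, max_events = 1e7) {
  stopifnot(inherits(rates, "logistic_rates"))
  if (!is.null(het)) stopifnot(inherits(het, "heterogeneity_spec"))
  if (n_worms < 0) abort("`n_worms` must be nonnegative")
  if (length(times) < 1 || any(times < 0)) abort("`times` must be nonnegative hours")
  times <- sort(unique(as.numeric(times)))
  if (n_worms == 0) {
    return(tibble(worm_id = character(), time_h = numeric(), load = numeric(),
                  condition = character(), true_b = numeric(),
                  true_c = numeric(), true_V = numeric()))
  }
  seeds <- derive_seeds(seed, n_worms)
  if (is.null(het)) {
    b_i <- rep(rates$b, n_worms)
    c_i <- rep(rates$c, n_worms)
    V_i <- rep(rates$V, n_worms)
  } else {
    b_i <- rtrunc_normal(n_worms, het$birth_mean, het$birth_sd)
    c_i <- rtrunc_normal(n_worms, het$colonization_mean, het$colonization_sd)
    V_i <- if (is.null(het$capacity_pool)) rep(rates$V, n_worms) else
      sample(het$capacity_pool, n_worms, replace = TRUE)
  }
  res <- purrr::map(seq_len(n_worms), function(i) {
    set.seed(seeds[i])
    gillespie_sample_cpp(b_i[i], c_i[i], rates$d, as.integer(round(V_i[i])),
                         as.integer(min(N0, V_i[i])), times, max_events)
  })
  tibble(
    worm_id = rep(sprintf("w%03d", seq_len(n_worms)), each = length(times)),
    time_h = rep(times, n_worms),
    load = as.numeric(unlist(res)),
    condition = condition,
    true_b = rep(b_i, each = length(times)),
    true_c = rep(c_i, each = length(times)),
    true_V = rep(as.numeric(round(V_i)), each = length(times))
  )
}
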