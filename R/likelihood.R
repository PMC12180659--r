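#' Fraction of uncolonized worms per time point
#'
#' Computes the "zero occupancy" fraction p_j at each time point together
#' with its binomial standard deviation sqrt(N p (1 - p)) / N, also expressed
#' as percentages for direct comparison with plotted error bars.
#'
#' @param snapshot A snapshot data frame (`worm_id`, `time_h`, `load`,
#'   `condition`).
#' @return A tibble with one row per time point: `time_h`, `n`, `n_zero`,
#'   `p_zero`, `sd_zero`, `pct_zero`, `pct_sd`.
#' @examples
#' snap <- tibble::tibble(worm_id = sprintf("w%d", 1:24), time_h = 12,
#'                        load = c(rep(0, 6), rep(100, 18)), condition = "x")
#' zero_occupancy(snap)
#' @export
zero_occupancy <- function(snapshot) {
  assert_snapshot(snapshot)
  if (nrow(snapshot) == 0) abort("empty snapshot")
  out <- dplyr::summarise(
    dplyr::group_by(snapshot, .data$time_h),
    n = dplyr::n(),
    n_zero = sum(.data$load == 0),
    .groups = "drop"
  )
  dplyr::mutate(out,
    p_zero = .data$n_zero / .data$n,
    sd_zero = sqrt(.data$n * .data$p_zero * (1 - .data$p_zero)) / .data$n,
    pct_zero = 100 * .data$p_zero,
    pct_sd = 100 * .data$sd_zero
  )
}

#' Discretize loads into low/medium/high levels
#'
#' Assigns each worm-time record to one of three bacterial-load levels given
#' two increasing cut points. Boundary values belong to the lower level, so
#' with the strong-colonizer cuts `c(10^1.5, 10^4)` a load of exactly 10^1.5
#' is "low".
#'
#' @inheritParams zero_occupancy
#' @param thresholds Two strictly increasing load cut points.
#' @return A tibble of class `level_counts` with columns `time_h`, `level`
#'   (factor low/medium/high) and `n`, completed to include zero cells; the
#'   thresholds are attached as an attribute.
#' @export
discretize_loads <- function(snapshot, thresholds) {
  assert_snapshot(snapshot)
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    abort("`thresholds` must be two strictly increasing cut points")
  }
  lvls <- c("low", "medium", "high")
  if (nrow(snapshot) == 0) {
    out <- tibble(time_h = numeric(), level = factor(character(), levels = lvls),
                  n = integer())
  } else {
    lab <- cut(snapshot$load, breaks = c(-Inf, thresholds, Inf),
               labels = lvls, right = TRUE)
    out <- dplyr::count(
      tibble(time_h = snapshot$time_h, level = lab), .data$time_h, .data$level,
      name = "n"
    )
    out <- tidyr::complete(out, .data$time_h,
                           level = factor(lvls, levels = lvls),
                           fill = list(n = 0L))
    out <- dplyr::arrange(out, .data$time_h, .data$level)
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("level_counts", class(out))
  out
}

#' Negative log-likelihood of discretized load counts
#'
#' NLL = -sum_ij n_ij log P_ij (natural log), where n_ij counts worms at
#' level i and time j and P_ij is the model probability of that cell. Cells
#' with zero model probability are floored at `floor` (continuity-correction
#' pseudocount, typically `1 / (2 n_sim)` for probabilities estimated from
#' `n_sim` simulated worms) and renormalized per time point, since otherwise
#' the likelihood is infinite whenever a finite simulation misses a level.
#'
#' @param observed A `level_counts` tibble from [discretize_loads()].
#' @param model_probs A tibble with columns `time_h`, `level`, `p`; per-time
#'   probabilities over the same levels.
#' @param floor Lower floor applied to probabilities before renormalization.
#' @return The negative log-likelihood (a single number).
#' @export
negative_log_likelihood <- function(observed, model_probs, floor = 0) {
  stopifnot(is.data.frame(observed), is.data.frame(model_probs))
  probs <- dplyr::mutate(
    dplyr::group_by(model_probs, .data$time_h),
    p = pmax(.data$p, floor),
    p = .data$p / sum(.data$p)
  )
  probs <- dplyr::ungroup(probs)
  joined <- dplyr::inner_join(
    tibble(time_h = observed$time_h, level = as.character(observed$level),
           n = observed$n),
    tibble(time_h = probs$time_h, level = as.character(probs$level),
           p = probs$p),
    by = c("time_h", "level")
  )
  if (nrow(joined) < nrow(observed)) {
    abort("`model_probs` is missing cells present in `observed`")
  }
  used <- joined[joined$n > 0, , drop = FALSE]
  if (any(used$p <= 0)) {
    abort("observed cells with zero model probability; supply a positive `floor`")
  }
  -sum(used$n * log(used$p))
}

# Estimate per-level probabilities at the snapshot's times from a simulated
# ensemble.
level_probs <- function(sim_snapshot, thresholds) {
  counts <- discretize_loads(sim_snapshot, thresholds)
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(counts, .data$time_h), p = .data$n / sum(.data$n)
  ))[, c("time_h", "level", "p")]
}

#' Grid search over heterogeneous-rate models
#'
#' For each candidate heterogeneity specification, simulates an ensemble,
#' estimates the per-level per-time probabilities of the three load levels,
#' and scores the observed data by discretized negative log-likelihood. At
#' the best grid point, the NLL distribution over repeated simulated
#' datasets of the data's own size is computed so the data's NLL can be
#' compared against what the model itself produces; the model is flagged
#' `rejected` when the data's NLL exceeds the 97.5th percentile of that
#' distribution.
#'
#' @param snapshot Observed snapshot data frame.
#' @param grid Data frame of candidate parameters; columns among
#'   `birth_mean`, `birth_sd`, `colonization_mean`, `colonization_sd`
#'   (missing columns default to 0 sd / the values in `rates`).
#' @param rates Baseline [logistic_rates()] supplying `d` and `V` (and any
#'   rate not varied in `grid`).
#' @param thresholds Two load cut points defining low/medium/high.
#' @param capacity_pool Optional capacity pool passed to every candidate.
#' @param n_worms_sim Worms per probability-estimation simulation; defaults
#'   to the number of worms per time point in the data.
#' @param n_rep Simulated datasets used for the NLL distribution at the
#'   optimum.
#' @param seed Master seed.
#' @return A list of class `grid_search_fit`: `best` (the winning grid row),
#'   `grid` (all rows with their NLL), `nll_data`, `nll_sim` (distribution at
#'   the optimum), `rejected`, `thresholds`.
#' @export
grid_search_heterogeneous <- function(snapshot, grid, rates, thresholds,
                                      capacity_pool = NULL,
                                      n_worms_sim = NULL, n_rep = 50,
                                      seed = NULL) {
  assert_snapshot(snapshot)
  if (!is.data.frame(grid) || nrow(grid) == 0) abort("`grid` must be a nonempty data frame")
  stopifnot(inherits(rates, "logistic_rates"))
  times <- sort(unique(snapshot$time_h))
  n_data <- nrow(snapshot) / length(times)
  n_sim <- n_worms_sim %||% round(n_data)
  floor_p <- 1 / (2 * n_sim)
  obs <- discretize_loads(snapshot, thresholds)
  seeds <- derive_seeds(seed, nrow(grid) + n_rep + 1)

  spec_of <- function(row) {
    heterogeneity_spec(
      birth_mean = row$birth_mean %||% rates$b,
      birth_sd = row$birth_sd %||% 0,
      colonization_mean = row$colonization_mean %||% rates$c,
      colonization_sd = row$colonization_sd %||% 0,
      capacity_pool = capacity_pool
    )
  }
  nll <- vapply(seq_len(nrow(grid)), function(i) {
    het <- spec_of(as.list(grid[i, , drop = FALSE]))
    sim <- simulate_ensemble(rates, het, n_worms = n_sim, times = times,
                             seed = seeds[i])
    negative_log_likelihood(obs, level_probs(sim, thresholds), floor = floor_p)
  }, numeric(1))

  best_i <- which.min(nll)
  best_het <- spec_of(as.list(grid[best_i, , drop = FALSE]))
  big <- simulate_ensemble(rates, best_het, n_worms = n_sim, times = times,
                           seed = seeds[nrow(grid) + 1])
  probs_best <- level_probs(big, thresholds)
  nll_sim <- vapply(seq_len(n_rep), function(r) {
    simr <- simulate_ensemble(rates, best_het, n_worms = round(n_data),
                              times = times, seed = seeds[nrow(grid) + 1 + r])
    negative_log_likelihood(discretize_loads(simr, thresholds), probs_best,
                            floor = floor_p)
  }, numeric(1))
  nll_data <- negative_log_likelihood(obs, probs_best, floor = floor_p)

  structure(list(
    best = tibble::as_tibble(grid[best_i, , drop = FALSE]),
    grid = dplyr::mutate(tibble::as_tibble(grid), nll = nll),
    nll_data = nll_data,
    nll_sim = nll_sim,
    rejected = nll_data > quantile(nll_sim, 0.975, names = FALSE),
    thresholds = thresholds
  ), class = "grid_search_fit")
}

#' @export
print.grid_search_fit <- function(x, ...) {
  cat("<grid_search_fit>\n best grid point:\n")
  print(x$best)
  cat(sprintf(" data NLL = %.3f vs simulated NLL median %.3f [97.5%%: %.3f]; %s\n",
              x$nll_data, median(x$nll_sim),
              quantile(x$nll_sim, 0.975, names = FALSE),
              if (x$rejected) "model REJECTED" else "model not rejected"))
  invisible(x)
}
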