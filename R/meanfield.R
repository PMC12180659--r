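#' Mean-field rate of change of gut occupancy
#'
#' The deterministic limit of the colonization/birth/death model for the mean
#' occupancy fraction phi = <N/V>:
#' dphi/dt = (1 - phi)(b phi + c) - d phi.
#'
#' @param phi Occupancy fraction in \[0, 1\] (vectorized).
#' @param rates A [logistic_rates()] object.
#' @return The rate of change of phi, 1/h.
#' @examples
#' meanfield_rhs(0.75, logistic_rates(b = 1, c = 0, d = 0.25, V = 1000))
#' @export
meanfield_rhs <- function(phi, rates) {
  stopifnot(inherits(rates, "logistic_rates"))
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1)) {
    abort("`phi` must lie in [0, 1]")
  }
  (1 - phi) * (rates$b * phi + rates$c) - rates$d * phi
}

#' Integrate the mean-field occupancy ODE
#'
#' Solves the deterministic mean-field equation with an adaptive
#' stiff-capable integrator ([deSolve::ode()], `lsoda`).
#'
#' @inheritParams meanfield_rhs
#' @param phi0 Initial occupancy fraction in \[0, 1\].
#' @param times Hours at which to report the solution; nonempty, increasing,
#'   nonnegative.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time_h` and `phi` (the trajectory is
#'   clamped to \[0, 1\] only to absorb solver round-off at the boundaries).
#' @examples
#' solve_meanfield(logistic_rates(1, 0.05, 0.2, 1000), 0, times = 0:48)
#' @export
solve_meanfield <- function(rates, phi0, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(rates, "logistic_rates"))
  assert_number(phi0, "phi0", lower = 0, upper = 1)
  if (length(times) < 1 || any(diff(times) <= 0) || any(times < 0)) {
    abort("`times` must be nonempty, nonnegative and strictly increasing")
  }
  t_solve <- times
  prepend <- times[1] > 0
  if (prepend) t_solve <- c(0, times)
  sol <- deSolve::ode(
    y = c(phi = phi0), times = t_solve,
    func = function(t, y, parms) {
      phi <- min(max(y[[1]], 0), 1)
      list((1 - phi) * (rates$b * phi + rates$c) - rates$d * phi)
    },
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol
  )
  diagn <- attributes(sol)$istate
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(sprintf("mean-field ODE integration failed (istate = %d)", diagn[1]))
  }
  phi <- pmin(pmax(sol[, "phi"], 0), 1)
  if (prepend) phi <- phi[-1]
  tibble(time_h = as.numeric(times), phi = as.numeric(phi))
}

#' Migration-free steady-state bacterial load
#'
#' In the migration-free regime (c = 0) with b > d, the stable steady state
#' of the mean-field model is N* = V (1 - d/b).
#'
#' @inheritParams meanfield_rhs
#' @return Steady-state load in cells.
#' @examples
#' steady_state_load(logistic_rates(b = 1, c = 0, d = 0.5, V = 1000))
#' @export
steady_state_load <- function(rates) {
  stopifnot(inherits(rates, "logistic_rates"))
  if (rates$b <= rates$d) {
    abort("no positive steady state: requires b > d in the migration-free regime")
  }
  rates$V * (1 - rates$d / rates$b)
}

#' Fit the mean-field model to snapshot means
#'
#' Least-squares fit of the integrated mean-field trajectory to per-time mean
#' loads, in log10 space (fluctuations of bacterial load are close to
#' symmetric on the log scale). Means are taken on raw loads before logging;
#' time points whose mean load is zero are excluded. Because birth and death
#' partially compensate each other in this model, the net growth rate b - d
#' is reported alongside the individual rates.
#'
#' @param snapshot A snapshot data frame with columns `worm_id`, `time_h`,
#'   `load`, `condition`.
#' @param V_fixed Carrying capacity to hold fixed during the fit; defaults to
#'   the maximum observed load.
#' @param phi0 Initial occupancy fraction (hosts start germ-free: 0).
#' @param start Optional named list of starting values for `b`, `c`, `d`.
#' @return A [logistic_rates()] object of class
#'   `c("meanfield_fit", "logistic_rates")` with attributes `residual`
#'   (residual sum of squares in log10 space), `n_points`, `b_minus_d`, and
#'   `fitted` (tibble of per-time observed and fitted log10 mean load).
#' @export
fit_meanfield <- function(snapshot, V_fixed = NULL, phi0 = 0, start = NULL) {
  assert_snapshot(snapshot)
  means <- dplyr::summarise(
    dplyr::group_by(snapshot, .data$time_h),
    mean_load = mean(.data$load), .groups = "drop"
  )
  means <- dplyr::arrange(dplyr::filter(means, .data$mean_load > 0), .data$time_h)
  if (nrow(means) == 0) abort("degenerate data: all loads are zero")
  if (nrow(means) < 3) abort("need >= 3 time points with positive mean load")
  V <- V_fixed %||% max(snapshot$load)
  if (V < 1) abort("degenerate data: carrying capacity would be < 1 cell")
  y <- log10(means$mean_load)
  tt <- means$time_h

  model_logload <- function(b, c, d) {
    rates <- logistic_rates(b, c, d, round(V))
    phi <- solve_meanfield(rates, phi0, tt)$phi
    log10(pmax(phi * V, .Machine$double.xmin))
  }
  # crude initialization from early-time slope and a small immigration rate
  start <- start %||% list(
    b = max(diff(range(y)) / diff(range(tt)) * log(10), 0.1),
    c = 1e-4, d = 0.05
  )
  obj <- function(par) {
    p <- exp(par)
    sum((y - model_logload(p[1], p[2], p[3]))^2)
  }
  fit <- optim(log(unlist(start)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  p <- unname(exp(fit$par))
  out <- logistic_rates(p[1], p[2], p[3], round(V))
  class(out) <- c("meanfield_fit", class(out))
  attr(out, "residual") <- fit$value
  attr(out, "n_points") <- nrow(means)
  attr(out, "b_minus_d") <- p[1] - p[3]
  attr(out, "convergence") <- fit$convergence
  attr(out, "fitted") <- tibble(
    time_h = tt, log10_mean_load = y,
    log10_fitted = model_logload(p[1], p[2], p[3])
  )
  out
}

#' @export
print.meanfield_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  mean-field fit: residual (log10 SSE) = %.4g on %d time points\n",
              attr(x, "residual"), attr(x, "n_points")))
  invisible(x)
}

#' Tidy a mean-field fit
#'
#' @param x A `meanfield_fit` object.
#' @param ... Unused.
#' @return One row per parameter (`b`, `c`, `d`, `b_minus_d`, `V`).
#' @export
tidy.meanfield_fit <- function(x, ...) {
  tibble(
    term = c("b", "c", "d", "b_minus_d", "V"),
    estimate = c(x$b, x$c, x$d, attr(x, "b_minus_d"), x$V)
  )
}

#' @rdname tidy.meanfield_fit
#' @export
glance.meanfield_fit <- function(x, ...) {
  tibble(residual = attr(x, "residual"), n_points = attr(x, "n_points"),
         convergence = attr(x, "convergence"))
}
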