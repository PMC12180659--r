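#' Two-state switching model of log bacterial load
#'
#' Each host-microbe system occupies a "low" or "high" growth state; within a
#' state, log10 load phi follows a logistic SDE
#' dphi = r_s phi (C_s - phi) dt + sqrt(D_s) dW, and the state flips
#' low -> high at rate `alpha_h` and high -> low at rate `alpha_l`
#' (a telegraph process).
#'
#' @param r_low,r_high Per-state growth rates (1/h per log-load unit, >= 0).
#' @param C_low,C_high Per-state carrying capacities in log10-load units,
#'   with `C_low < C_high`.
#' @param D_low,D_high Per-state noise variances (log-load^2/h, > 0).
#' @param alpha_h Low-to-high switching rate (1/h, >= 0).
#' @param alpha_l High-to-low switching rate (1/h, >= 0).
#' @return An object of class `switching_model`.
#' @examples
#' switching_model(1, 2, 0.2, 1, 5.5, 0.2, alpha_h = 0.08, alpha_l = 0.02)
#' @export
switching_model <- function(r_low, C_low, D_low, r_high, C_high, D_high,
                            alpha_h, alpha_l) {
  for (nm in c("r_low", "r_high", "alpha_h", "alpha_l")) {
    assert_number(get(nm), nm, lower = 0)
  }
  assert_number(D_low, "D_low")
  assert_number(D_high, "D_high")
  if (D_low <= 0 || D_high <= 0) abort("noise variances must be positive")
  if (C_low >= C_high) abort("`C_low` must be below `C_high`")
  structure(list(r_low = r_low, C_low = C_low, D_low = D_low,
                 r_high = r_high, C_high = C_high, D_high = D_high,
                 alpha_h = alpha_h, alpha_l = alpha_l),
            class = "switching_model")
}

#' @export
print.switching_model <- function(x, ...) {
  cat(sprintf(
    "<switching_model> low: r = %g, C = %g, D = %g | high: r = %g, C = %g, D = %g\n",
    x$r_low, x$C_low, x$D_low, x$r_high, x$C_high, x$D_high))
  cat(sprintf("  alpha_h (low->high) = %g /h, alpha_l (high->low) = %g /h; stationary P(high) = %.3f\n",
              x$alpha_h, x$alpha_l, x$alpha_h / (x$alpha_h + x$alpha_l)))
  invisible(x)
}

#' Serialize a switching model to/from JSON
#' @param model A [switching_model()].
#' @param path File path.
#' @export
write_switching_json <- function(model, path) {
  stopifnot(inherits(model, "switching_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_switching_json
#' @export
read_switching_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(switching_model, rec[c("r_low", "C_low", "D_low", "r_high",
                                 "C_high", "D_high", "alpha_h", "alpha_l")])
}

#' Closed-form occupancy relaxation of the two-state master equation
#'
#' The probability of occupying the high state relaxes exponentially:
#' P(high, t) = A exp(-(alpha_h + alpha_l) t) + alpha_h/(alpha_h + alpha_l),
#' with A fixed by the initial occupancy `p0`.
#'
#' @param alpha_h,alpha_l Switching rates (1/h), with `alpha_h + alpha_l > 0`.
#' @param p0 Initial high-state probability in \[0, 1\].
#' @param times Hours.
#' @return A tibble of class `occupancy_curve` with `time_h` and `p_high`.
#' @examples
#' occupancy_solution(0.08, 0.02, p0 = 0, times = c(0, 6, 24, 48, 72))
#' @export
occupancy_solution <- function(alpha_h, alpha_l, p0, times) {
  assert_number(alpha_h, "alpha_h", lower = 0)
  assert_number(alpha_l, "alpha_l", lower = 0)
  if (alpha_h + alpha_l <= 0) abort("`alpha_h + alpha_l` must be positive")
  assert_number(p0, "p0", lower = 0, upper = 1)
  p_inf <- alpha_h / (alpha_h + alpha_l)
  p <- (p0 - p_inf) * exp(-(alpha_h + alpha_l) * times) + p_inf
  out <- tibble(time_h = as.numeric(times), p_high = pmin(pmax(p, 0), 1))
  class(out) <- c("occupancy_curve", class(out))
  out
}

#' Fit switching rates to an occupancy curve
#'
#' Nonlinear least squares of the occupancy relaxation to observed high-state
#' fractions over time (e.g. the high-mode weights of per-time mixture
#' fits), with rates constrained nonnegative. The initial occupancy is a
#' free parameter by default; fix it by passing `p0`.
#'
#' @param curve Data frame with columns `time_h` and `p_high` (>= 3 rows).
#' @param p0 Optional fixed initial occupancy.
#' @return A list of class `switching_fit`: `alpha_h`, `alpha_l`, `p0`,
#'   `residual` (sum of squares), `identifiable` (FALSE when the curve is
#'   flat so only the ratio alpha_h/alpha_l is determined), and `fitted`.
#' @export
fit_switching_rates <- function(curve, p0 = NULL) {
  if (!is.data.frame(curve) || !all(c("time_h", "p_high") %in% names(curve))) {
    abort("`curve` must have columns time_h and p_high")
  }
  if (nrow(curve) < 3) abort("need >= 3 time points")
  dat <- data.frame(t = curve$time_h, p = curve$p_high)
  flat <- sd(dat$p) < 1e-8
  if (flat) {
    # no transient: only alpha_h/alpha_l is determined (by the plateau);
    # report the ratio-consistent pair with unit total rate
    p_star <- mean(dat$p)
    warn("occupancy curve is constant: only the ratio alpha_h/alpha_l is identifiable")
    return(structure(list(
      alpha_h = p_star, alpha_l = 1 - p_star, p0 = p_star, residual = 0,
      identifiable = FALSE,
      fitted = tibble(time_h = dat$t, p_high = dat$p, p_fitted = p_star)
    ), class = "switching_fit"))
  }
  p_inf_guess <- dat$p[which.max(dat$t)]
  rate_guess <- max(1 / max(dat$t), 0.05)
  fit <- tryCatch({
    if (is.null(p0)) {
      minpack.lm::nlsLM(
        p ~ (p0f - ah / (ah + al)) * exp(-(ah + al) * t) + ah / (ah + al),
        data = dat,
        start = list(ah = p_inf_guess * rate_guess + 1e-3,
                     al = (1 - p_inf_guess) * rate_guess + 1e-3,
                     p0f = dat$p[which.min(dat$t)]),
        lower = c(ah = 0, al = 0, p0f = 0), upper = c(Inf, Inf, 1),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    } else {
      assert_number(p0, "p0", lower = 0, upper = 1)
      minpack.lm::nlsLM(
        p ~ (p0 - ah / (ah + al)) * exp(-(ah + al) * t) + ah / (ah + al),
        data = dat,
        start = list(ah = p_inf_guess * rate_guess + 1e-3,
                     al = (1 - p_inf_guess) * rate_guess + 1e-3),
        lower = c(ah = 0, al = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    }
  }, error = function(e) abort(paste0("switching-rate fit failed to converge: ",
                                      conditionMessage(e))))
  est <- coef(fit)
  out <- structure(list(
    alpha_h = est[["ah"]], alpha_l = est[["al"]],
    p0 = if (is.null(p0)) est[["p0f"]] else p0,
    residual = sum(residuals(fit)^2),
    identifiable = !flat,
    fitted = tibble(time_h = dat$t, p_high = dat$p,
                    p_fitted = as.numeric(fitted(fit)))
  ), class = "switching_fit")
  out
}

#' @export
print.switching_fit <- function(x, ...) {
  cat(sprintf("<switching_fit> alpha_h = %.4g /h, alpha_l = %.4g /h, p0 = %.3f (SSE %.3g)%s\n",
              x$alpha_h, x$alpha_l, x$p0, x$residual,
              if (x$identifiable) "" else " [ratio-only identifiable]"))
  invisible(x)
}

#' Tidy a switching-rate fit
#' @param x A `switching_fit`.
#' @param ... Unused.
#' @export
tidy.switching_fit <- function(x, ...) {
  tibble(term = c("alpha_h", "alpha_l", "p0"),
         estimate = c(x$alpha_h, x$alpha_l, x$p0))
}

#' @rdname tidy.switching_fit
#' @export
glance.switching_fit <- function(x, ...) {
  tibble(residual = x$residual, identifiable = x$identifiable,
         p_high_stationary = x$alpha_h / (x$alpha_h + x$alpha_l))
}

#' Simulate the switching SDE (Euler-Maruyama)
#'
#' Integrates the per-state logistic SDE with per-step state flips. In the
#' default `"bernoulli"` mode the flip probability per step is alpha dt,
#' matching a first-order discretization of the telegraph process; the
#' `"exact"` mode uses 1 - exp(-alpha dt), the exact per-step marginal for a
#' constant rate. Log-load is reflected at 0 (loads below one cell are not
#' meaningful on the log scale).
#'
#' @param model A [switching_model()].
#' @param phi0 Initial log10 load.
#' @param s0 Initial state, `"low"` or `"high"`.
#' @param t_end Hours to simulate.
#' @param dt Time step in hours; errors if `max(alpha) * dt > 0.1`.
#' @param seed Seed.
#' @param record_every Record every this many steps.
#' @param method Flip discretization, `"bernoulli"` or `"exact"`.
#' @param reflect Reflect log-load at zero (default TRUE).
#' @return Tibble with columns `time_h`, `phi`, `state` ("low"/"high").
#' @export
simulate_switching <- function(model, phi0, s0 = c("low", "high"), t_end,
                               dt = 0.01, seed = NULL, record_every = 1L,
                               method = c("bernoulli", "exact"),
                               reflect = TRUE) {
  stopifnot(inherits(model, "switching_model"))
  s0 <- match.arg(s0)
  method <- match.arg(method)
  assert_number(dt, "dt")
  if (dt <= 0) abort("`dt` must be positive")
  if (max(model$alpha_h, model$alpha_l) * dt > 0.1) {
    abort("`dt` too large: max(alpha_h, alpha_l) * dt must not exceed 0.1")
  }
  res <- with_seed(seed, sim_switching_cpp(
    model$r_low, model$C_low, model$D_low,
    model$r_high, model$C_high, model$D_high,
    model$alpha_h, model$alpha_l,
    phi0, as.integer(s0 == "high"), t_end, dt, as.integer(record_every),
    method == "exact", reflect
  ))
  tibble(time_h = res$time_h, phi = res$phi,
         state = c("low", "high")[res$state + 1])
}

#' Exact simulation of the two-state telegraph process at observation times
#'
#' Samples `n` independent two-state Markov chains exactly at the requested
#' times using the closed-form interval transition probabilities of the
#' telegraph process, and returns per-time high-state occupancy fractions.
#' Serves as an oracle for the master-equation solution and as the
#' generating process for occupancy-refit studies.
#'
#' @inheritParams occupancy_solution
#' @param n Number of chains.
#' @param times Observation times (hours, increasing; first may be 0).
#' @param seed Seed.
#' @return Tibble with `time_h`, `n`, `n_high`, `p_high`.
#' @export
simulate_telegraph <- function(alpha_h, alpha_l, p0, n, times, seed = NULL) {
  assert_number(alpha_h, "alpha_h", lower = 0)
  assert_number(alpha_l, "alpha_l", lower = 0)
  if (alpha_h + alpha_l <= 0) abort("`alpha_h + alpha_l` must be positive")
  assert_number(p0, "p0", lower = 0, upper = 1)
  times <- sort(as.numeric(times))
  if (!is.null(seed)) set.seed(seed)
  a <- alpha_h + alpha_l
  p_inf <- alpha_h / a
  state <- runif(n) < p0  # TRUE = high
  t_prev <- 0
  res <- purrr::map(seq_along(times), function(k) {
    dt_k <- times[k] - t_prev
    if (dt_k > 0) {
      decay <- exp(-a * dt_k)
      # P(high at t + dt | current state)
      p_hh <- p_inf + (1 - p_inf) * decay
      p_lh <- p_inf * (1 - decay)
      p_trans <- ifelse(state, p_hh, p_lh)
      state <<- runif(n) < p_trans
    }
    t_prev <<- times[k]
    tibble(time_h = times[k], n = n, n_high = sum(state),
           p_high = mean(state))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("occupancy_curve", class(out))
  out
}

#' Fast-switching stationary density of the switching model
#'
#' Mixture of the two per-state Boltzmann densities,
#' A_s exp(r_s phi^2 (C_s/2 - phi/3) / D_s), weighted by the stationary
#' state probabilities alpha_h/(alpha_h+alpha_l) (high) and
#' alpha_l/(alpha_h+alpha_l) (low). Each component is normalized by numeric
#' quadrature on the working support `[0, C_high + 4 sqrt(D_high/r_high)]`.
#' The approximation treats each state as internally equilibrated.
#'
#' @param model A [switching_model()].
#' @param support Optional length-2 numeric support for normalization.
#' @return A function of phi (log10 load) returning the stationary density,
#'   with the support attached as an attribute.
#' @export
switching_stationary_pdf <- function(model, support = NULL) {
  stopifnot(inherits(model, "switching_model"))
  support <- support %||%
    c(0, model$C_high + 4 * sqrt(model$D_high / max(model$r_high, 1e-12)))
  comp <- function(r, C, D) {
    f <- function(phi) exp(r * phi^2 * (C / 2 - phi / 3) / D -
                             r * C^3 / 6 / D)  # shift by the well minimum for stability
    Z <- integrate(f, support[1], support[2], rel.tol = 1e-10)$value
    function(phi) ifelse(phi >= support[1] & phi <= support[2], f(phi) / Z, 0)
  }
  f_low <- comp(model$r_low, model$C_low, model$D_low)
  f_high <- comp(model$r_high, model$C_high, model$D_high)
  w_high <- model$alpha_h / (model$alpha_h + model$alpha_l)
  out <- function(phi) (1 - w_high) * f_low(phi) + w_high * f_high(phi)
  attr(out, "support") <- support
  out
}
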