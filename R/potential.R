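#' Polynomial multiwell potential
#'
#' Overdamped Langevin dynamics of log10 load on a scalar landscape:
#' dphi = -U'(phi) dt + sqrt(D) dW. A bistable U has two minima (the stable
#' low and high load states) separated by one interior maximum (the
#' barrier).
#'
#' @param coefficients Polynomial coefficients of U(phi), ascending
#'   (constant first); order 4 or 6 in typical use.
#' @param D Noise variance (log-load^2/h, > 0); may be `NA` for potentials
#'   fitted on the R = U/D scale before [estimate_noise_D()].
#' @param scale Either `"U"` (absolute potential) or `"R"` (potential in
#'   units of D, as fitted from -log density).
#' @return An object of class `poly_potential`.
#' @examples
#' # symmetric double well (phi^2 - 1)^2 / 4
#' poly_potential(c(0.25, 0, -0.5, 0, 0.25), D = 0.05)
#' @export
poly_potential <- function(coefficients, D = NA_real_, scale = c("U", "R")) {
  scale <- match.arg(scale)
  if (!is.numeric(coefficients) || length(coefficients) < 3) {
    abort("`coefficients` must be a numeric vector (ascending powers, order >= 2)")
  }
  if (!is.na(D)) assert_number(D, "D")
  if (!is.na(D) && D <= 0) abort("`D` must be positive")
  structure(list(coefficients = as.numeric(coefficients), D = D, scale = scale),
            class = "poly_potential")
}

poly_eval <- function(coef, x) {
  out <- 0
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

poly_deriv <- function(coef) {
  n <- length(coef)
  if (n <= 1) return(0)
  coef[-1] * seq_len(n - 1)
}

#' Evaluate a polynomial potential and its derivatives
#' @param pot A [poly_potential()].
#' @param phi Log10-load values.
#' @param deriv Derivative order (0, 1 or 2).
#' @return U(phi) (or U', U'') at `phi`.
#' @export
potential_value <- function(pot, phi, deriv = 0) {
  stopifnot(inherits(pot, "poly_potential"))
  coef <- pot$coefficients
  for (k in seq_len(deriv)) coef <- poly_deriv(coef)
  poly_eval(coef, phi)
}

#' @export
print.poly_potential <- function(x, ...) {
  cat(sprintf("<poly_potential> order %d (%s scale), D = %s\n",
              length(x$coefficients) - 1, x$scale,
              if (is.na(x$D)) "unset" else format(x$D)))
  cat("  coefficients (ascending):", signif(x$coefficients, 4), "\n")
  invisible(x)
}

#' Serialize a polynomial potential to/from JSON
#' @param pot A [poly_potential()].
#' @param path File path.
#' @export
write_potential_json <- function(pot, path) {
  stopifnot(inherits(pot, "poly_potential"))
  jsonlite::write_json(
    list(order = length(pot$coefficients) - 1,
         coefficients = pot$coefficients, D = pot$D, scale = pot$scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potential_json
#' @export
read_potential_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly_potential(rec$coefficients, D = rec$D %||% NA_real_,
                 scale = rec$scale %||% "U")
}

#' Empirical effective potential from log-load values
#'
#' Histograms the data and returns R(phi) = -ln density on the nonempty
#' bins: the landscape a stationary overdamped process would need (in units
#' of its noise variance D) to produce the observed density. Empty bins are
#' excluded, not imputed.
#'
#' @param values Log10-load values (>= 50).
#' @param n_bins Number of equal-width bins over the data range.
#' @return A tibble of class `effective_potential` with columns `phi` (bin
#'   centers), `R`, `count`, and a `breaks` attribute.
#' @export
empirical_effective_potential <- function(values, n_bins = 40) {
  values <- values[is.finite(values)]
  if (length(values) < 50) abort("need >= 50 values for an effective potential")
  h <- graphics::hist(values, breaks = seq(min(values), max(values),
                                           length.out = n_bins + 1),
                      plot = FALSE)
  keep <- h$counts > 0
  out <- tibble(phi = h$mids[keep], R = -log(h$density[keep]),
                count = h$counts[keep])
  attr(out, "breaks") <- h$breaks
  class(out) <- c("effective_potential", class(out))
  out
}

#' Fit a polynomial potential to an effective potential
#'
#' Count-weighted least squares of an even-order polynomial (order >= 4) to
#' R(phi) over the nonempty bins, so sparsely populated tails do not
#' dominate the fit. Two modes in the data require order >= 4; order 6
#' additionally captures unequal widths of the two wells. The returned
#' potential is on the R = U/D scale; combine with [estimate_noise_D()] to
#' obtain absolute U and D.
#'
#' @param eff An `effective_potential` tibble.
#' @param order Polynomial order, even and >= 4.
#' @return A [poly_potential()] (scale `"R"`) with attributes `residual`
#'   (weighted SSE), `bistable` (classification on the working support) and
#'   `support`.
#' @export
fit_polynomial_potential <- function(eff, order = 6) {
  stopifnot(inherits(eff, "effective_potential"))
  if (order %% 2 != 0 || order < 4) abort("`order` must be even and >= 4")
  X <- outer(eff$phi, 0:order, `^`)
  fit <- stats::lm.wfit(X, eff$R, w = eff$count)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  pot <- poly_potential(coefs, D = NA_real_, scale = "R")
  if (coefs[order + 1] <= 0) {
    warn("fitted potential is non-confining (leading coefficient <= 0)")
  }
  support <- range(eff$phi) + c(-1, 1)
  fp <- tryCatch(find_fixed_points(pot, support = support),
                 error = function(e) NULL)
  attr(pot, "residual") <- sum(eff$count * fit$residuals^2)
  attr(pot, "bistable") <- !is.null(fp)
  attr(pot, "support") <- support
  attr(pot, "fixed_points") <- fp
  pot
}

#' Fixed points and curvatures of a bistable potential
#'
#' Finds the real roots of U' on the working support, classifies them by the
#' sign of U'', and returns the two minima (`C_L`, `C_H`) flanking one
#' interior maximum (`C_M`), with curvature magnitudes |U''|.
#'
#' @param pot A [poly_potential()].
#' @param support Length-2 working support for root finding; defaults to the
#'   fitted support when present.
#' @return A list of class `fixed_points`: `C_L`, `C_M`, `C_H`, `K_L`,
#'   `K_M`, `K_H`.
#' @examples
#' find_fixed_points(poly_potential(c(0.25, 0, -0.5, 0, 0.25), D = 0.05),
#'                   support = c(-2, 2))
#' @export
find_fixed_points <- function(pot, support = NULL) {
  stopifnot(inherits(pot, "poly_potential"))
  support <- support %||% attr(pot, "support") %||%
    abort("supply `support` for root finding")
  dcoef <- poly_deriv(pot$coefficients)
  roots <- polyroot(dcoef)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  real <- sort(unique(round(real, 10)))
  real <- real[real >= support[1] & real <= support[2]]
  if (length(real) == 0) abort("not bistable: no fixed points on the support")
  curv <- vapply(real, function(x) potential_value(pot, x, deriv = 2), numeric(1))
  minima <- real[curv > 0]
  maxima <- real[curv < 0]
  if (length(minima) != 2) {
    abort(sprintf("not bistable: found %d minima on the support (need exactly 2)",
                  length(minima)))
  }
  barrier <- maxima[maxima > min(minima) & maxima < max(minima)]
  if (length(barrier) != 1) {
    abort("not bistable: need exactly one interior maximum between the minima")
  }
  k <- function(x) abs(potential_value(pot, x, deriv = 2))
  structure(list(C_L = min(minima), C_M = barrier, C_H = max(minima),
                 K_L = k(min(minima)), K_M = k(barrier), K_H = k(max(minima))),
            class = "fixed_points")
}

#' @export
print.fixed_points <- function(x, ...) {
  cat(sprintf("<fixed_points> C_L = %.4g, C_M = %.4g, C_H = %.4g | K_L = %.4g, K_M = %.4g, K_H = %.4g\n",
              x$C_L, x$C_M, x$C_H, x$K_L, x$K_M, x$K_H))
  invisible(x)
}

#' Kramers escape rates of a bistable potential
#'
#' Asymptotic barrier-crossing rates of the overdamped dynamics:
#' alpha_l = sqrt(K_H K_M)/(2 pi) exp(-(U(C_M) - U(C_H))/D) for escape from
#' the high well, and the analogous expression from the low well. Valid when
#' barriers are large compared to D.
#'
#' @param pot A [poly_potential()] with `D` set (scale `"U"`).
#' @param fp Optional [find_fixed_points()] result; computed when missing.
#' @param support Support used if `fp` must be computed.
#' @return A tibble with `alpha_h`, `alpha_l`, and the two barrier heights.
#' @export
kramers_rates <- function(pot, fp = NULL, support = NULL) {
  stopifnot(inherits(pot, "poly_potential"))
  if (is.na(pot$D)) abort("`pot$D` must be set to compute Kramers rates")
  fp <- fp %||% find_fixed_points(pot, support = support)
  U <- function(x) potential_value(pot, x)
  dU_high <- U(fp$C_M) - U(fp$C_H)
  dU_low <- U(fp$C_M) - U(fp$C_L)
  if (dU_high <= 0 || dU_low <= 0) abort("barrier heights must be positive")
  tibble(
    alpha_h = sqrt(fp$K_L * fp$K_M) / (2 * pi) * exp(-dU_low / pot$D),
    alpha_l = sqrt(fp$K_H * fp$K_M) / (2 * pi) * exp(-dU_high / pot$D),
    barrier_low = dU_low, barrier_high = dU_high
  )
}

#' Estimate the noise amplitude from a measured escape rate
#'
#' Given a potential fitted on the R = U/D scale (from -log density) and an
#' independently measured high-to-low transition rate, inverts the Kramers
#' formula under U = D R: since |U''| = D |R''| and the barrier in units of
#' D equals the R-barrier,
#' D = 2 pi alpha_l exp(R(C_M) - R(C_H)) / sqrt(R''(C_H) R''(C_M)).
#'
#' @param eff_R A [poly_potential()] on the `"R"` scale.
#' @param fp Fixed points of the R-scale potential.
#' @param alpha_l Measured high-to-low rate (1/h, > 0).
#' @return The R-scale potential with `D` estimated, rescaled to an absolute
#'   potential (`scale = "U"`, coefficients multiplied by D).
#' @export
estimate_noise_D <- function(eff_R, fp = NULL, alpha_l, support = NULL) {
  stopifnot(inherits(eff_R, "poly_potential"))
  if (eff_R$scale != "R") abort("`eff_R` must be on the R = U/D scale")
  assert_number(alpha_l, "alpha_l")
  if (alpha_l <= 0) abort("`alpha_l` must be positive")
  fp <- fp %||% find_fixed_points(eff_R, support = support)
  R <- function(x) potential_value(eff_R, x)
  D <- 2 * pi * alpha_l * exp(R(fp$C_M) - R(fp$C_H)) / sqrt(fp$K_H * fp$K_M)
  out <- poly_potential(eff_R$coefficients * D, D = D, scale = "U")
  attr(out, "support") <- attr(eff_R, "support")
  out
}

#' Boltzmann stationary density of a confining potential
#'
#' P(phi) = A exp(-U(phi)/D), normalized by numeric quadrature on the
#' working support.
#'
#' @param pot A [poly_potential()] with `D` set.
#' @param support Length-2 normalization support; defaults to the potential's
#'   fitted support.
#' @return A density function of phi with the support attached.
#' @export
potential_stationary_pdf <- function(pot, support = NULL) {
  stopifnot(inherits(pot, "poly_potential"))
  if (is.na(pot$D)) abort("`pot$D` must be set")
  support <- support %||% attr(pot, "support") %||%
    abort("supply `support` for normalization")
  grid <- seq(support[1], support[2], length.out = 2001)
  u <- poly_eval(pot$coefficients, grid)
  u0 <- min(u)
  f <- function(phi) exp(-(poly_eval(pot$coefficients, phi) - u0) / pot$D)
  Z <- integrate(f, support[1], support[2], rel.tol = 1e-10)$value
  out <- function(phi) {
    ifelse(phi >= support[1] & phi <= support[2], f(phi) / Z, 0)
  }
  attr(out, "support") <- support
  out
}

#' Simulate the potential-model Langevin dynamics
#'
#' Euler-Maruyama integration of dphi = -U'(phi) dt + sqrt(D dt) xi, with a
#' blow-up guard that aborts if the trajectory leaves the working support by
#' more than ten support widths (a sign of a non-confining potential at the
#' chosen noise level).
#'
#' @param pot A [poly_potential()] with `D` set.
#' @param phi0 Initial log10 load.
#' @param t_end Hours.
#' @param dt Step, hours (> 0).
#' @param seed Seed.
#' @param record_every Record every this many steps.
#' @param support Working support for the guard; defaults to the fitted one.
#' @return Tibble with `time_h`, `phi`.
#' @export
simulate_potential <- function(pot, phi0, t_end, dt = 0.01, seed = NULL,
                               record_every = 1L, support = NULL) {
  stopifnot(inherits(pot, "poly_potential"))
  if (is.na(pot$D)) abort("`pot$D` must be set")
  if (dt <= 0) abort("`dt` must be positive")
  support <- support %||% attr(pot, "support") %||% (phi0 + c(-10, 10))
  width <- diff(support)
  dU <- poly_deriv(pot$coefficients)
  res <- with_seed(seed, sim_potential_cpp(
    dU, pot$D, phi0, t_end, dt, as.integer(record_every),
    support[1] - 10 * width, support[2] + 10 * width
  ))
  tibble(time_h = res$time_h, phi = res$phi)
}

#' Empirical first-passage escape rate
#'
#' Monte-Carlo oracle for [kramers_rates()]: repeated Langevin runs started
#' at one well bottom, absorbed at the opposite well bottom; the escape rate
#' is the reciprocal mean first-passage time.
#'
#' @param pot A [poly_potential()] with `D` set.
#' @param from,to Start and absorbing positions (well bottoms).
#' @param n_runs Number of runs.
#' @param dt Step, hours.
#' @param t_max Per-run time cap (censored runs count at `t_max`).
#' @param seed Seed.
#' @return A tibble with `rate`, `mean_fpt`, `n_censored`.
#' @export
first_passage_rate <- function(pot, from, to, n_runs = 500, dt = 0.005,
                               t_max = 1e5, seed = NULL) {
  stopifnot(inherits(pot, "poly_potential"))
  if (is.na(pot$D)) abort("`pot$D` must be set")
  dU <- poly_deriv(pot$coefficients)
  seeds <- derive_seeds(seed, n_runs)
  fpt <- vapply(seq_len(n_runs), function(i) {
    set.seed(seeds[i])
    first_passage_cpp(dU, pot$D, from, to, dt, t_max)
  }, numeric(1))
  n_cens <- sum(is.na(fpt))
  fpt[is.na(fpt)] <- t_max
  tibble(rate = 1 / mean(fpt), mean_fpt = mean(fpt), n_censored = n_cens)
}
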