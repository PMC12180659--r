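#' Two-component Gaussian mixture fit in log-CFU space
#'
#' Fits a two-component univariate Gaussian mixture by EM (via
#' \pkg{mclust} with unequal variances) to log10-load values. Components are
#' always reported sorted by mean (low, high). The mixture is interpreted as
#' a summary statistic of a bimodal load distribution, not as a partition of
#' worms; its high-mode weight is the occupancy proxy used downstream.
#'
#' @param values Numeric vector of log10 CFU values (>= 4 finite values).
#' @param seed Seed recorded for reproducibility (the EM initialization used
#'   here is deterministic, so the seed does not change the result).
#' @param var_floor Variance floor preventing collapse onto duplicated
#'   values.
#' @return An object of class `gmm2` with elements `w`, `mu`, `sigma` (each
#'   length 2, named `low`/`high`), `loglik`, `n`, and `degenerate` (TRUE
#'   with a warning when one weight < 1e-3 or a variance sits on the floor).
#' @examples
#' x <- c(rnorm(100, 2, 0.3), rnorm(100, 5.5, 0.4))
#' fit_gmm2(x, seed = 1)
#' @export
fit_gmm2 <- function(values, seed = NULL, var_floor = 1e-4) {
  values <- values[is.finite(values)]
  if (length(values) < 4) abort("need >= 4 finite values for a 2-component mixture")
  if (var(values) < var_floor) {
    # all values (numerically) identical: EM cannot separate components
    warn("degenerate mixture fit: a component weight or variance collapsed")
    return(structure(list(
      w = setNames(c(0.5, 0.5), c("low", "high")),
      mu = setNames(rep(mean(values), 2), c("low", "high")),
      sigma = setNames(rep(sqrt(var_floor), 2), c("low", "high")),
      loglik = sum(dnorm(values, mean(values), sqrt(var_floor), log = TRUE)),
      n = length(values), degenerate = TRUE
    ), class = "gmm2"))
  }
  # Mclust evaluates mclustBIC() in the caller's frame, so bind it locally
  mclustBIC <- mclust::mclustBIC
  fit <- with_seed(seed, suppressWarnings(
    mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE)
  ))
  if (is.null(fit)) abort("mixture fit failed")
  mu <- as.numeric(fit$parameters$mean)
  sig2 <- pmax(as.numeric(fit$parameters$variance$sigmasq), var_floor)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  out <- structure(list(
    w = setNames(w[ord], c("low", "high")),
    mu = setNames(mu[ord], c("low", "high")),
    sigma = setNames(sqrt(sig2[ord]), c("low", "high")),
    loglik = fit$loglik,
    n = length(values),
    degenerate = FALSE
  ), class = "gmm2")
  floor_hit <- any(as.numeric(fit$parameters$variance$sigmasq) <= var_floor)
  overlap <- abs(diff(out$mu)) < 0.5 * sum(out$sigma) / 2
  if (any(out$w < 1e-3) || floor_hit) {
    out$degenerate <- TRUE
    warn("degenerate mixture fit: a component weight or variance collapsed")
  }
  attr(out, "overlapping") <- overlap
  out
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf(
    "<gmm2> low: w = %.3f, mu = %.3f, sigma = %.3f | high: w = %.3f, mu = %.3f, sigma = %.3f\n",
    x$w[1], x$mu[1], x$sigma[1], x$w[2], x$mu[2], x$sigma[2]))
  cat(sprintf("  loglik = %.3f on n = %d%s\n", x$loglik, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Tidy a two-component mixture
#' @param x A `gmm2` object.
#' @param ... Unused.
#' @export
tidy.gmm2 <- function(x, ...) {
  tibble(component = c("low", "high"), weight = unname(x$w),
         mean = unname(x$mu), sd = unname(x$sigma))
}

#' @rdname tidy.gmm2
#' @export
glance.gmm2 <- function(x, ...) {
  tibble(loglik = x$loglik, n = x$n, degenerate = x$degenerate)
}

#' Mixture probability density
#'
#' @param gmm A `gmm2` object.
#' @param x Log10-load values at which to evaluate the density.
#' @return w_L Normal(mu_L, sigma_L) + w_H Normal(mu_H, sigma_H) at `x`.
#' @export
gmm_pdf <- function(gmm, x) {
  stopifnot(inherits(gmm, "gmm2"))
  gmm$w[["low"]] * dnorm(x, gmm$mu[["low"]], gmm$sigma[["low"]]) +
    gmm$w[["high"]] * dnorm(x, gmm$mu[["high"]], gmm$sigma[["high"]])
}

#' High-mode weight over time (occupancy proxy)
#'
#' Fits a two-component mixture independently at each time point of a
#' snapshot and returns the weight of the high-mean component, the proxy for
#' the probability of being in the high-load state.
#'
#' @param snapshot Snapshot data frame; `load` is taken as raw CFU unless
#'   `log_input = TRUE`.
#' @param seed Seed (for interface symmetry; fits are deterministic).
#' @param zeros How to handle zero loads before logging: `"exclude"` drops
#'   them, `"detection_limit"` maps them to log10(100), the approximate
#'   detection threshold of the fluorescence assay.
#' @param log_input Set TRUE if `load` already holds log10 values.
#' @return A tibble of class `occupancy_curve` with columns `time_h`,
#'   `p_high`, plus per-time mixture parameters (`w_low`, `mu_low`,
#'   `sigma_low`, `w_high`, `mu_high`, `sigma_high`, `degenerate`).
#' @export
weight_series <- function(snapshot, seed = NULL, zeros = c("exclude", "detection_limit"),
                          log_input = FALSE) {
  assert_snapshot(snapshot)
  zeros <- match.arg(zeros)
  times <- sort(unique(snapshot$time_h))
  if (length(times) < 2) abort("need >= 2 time points for a weight series")
  rows <- purrr::map(times, function(tt) {
    x <- snapshot$load[snapshot$time_h == tt]
    if (!log_input) {
      if (zeros == "detection_limit") x[x == 0] <- 100
      x <- log10(x[x > 0])
    }
    fit <- withCallingHandlers(
      fit_gmm2(x, seed = seed),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble(time_h = tt, p_high = fit$w[["high"]],
           w_low = fit$w[["low"]], mu_low = fit$mu[["low"]],
           sigma_low = fit$sigma[["low"]], w_high = fit$w[["high"]],
           mu_high = fit$mu[["high"]], sigma_high = fit$sigma[["high"]],
           degenerate = fit$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$degenerate)) {
    warn(sprintf("degenerate mixture fits at %d time point(s)", sum(out$degenerate)))
  }
  class(out) <- c("occupancy_curve", class(out))
  out
}
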