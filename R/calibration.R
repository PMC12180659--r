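#' Saturating log(CFU) to log(GFP) calibration map
#'
#' The fluorescence readout of a worm sorter compresses a wide range of
#' bacterial loads into a bounded optical signal. The calibration is modeled
#' as y(x) = a tanh((x - b) / c), with x = log10 CFU and y = log10 GFP:
#' linear at small loads and saturating at the device ceiling `a`.
#'
#' @param a Saturation amplitude (log-GFP units, > 0).
#' @param b Center (log-CFU units).
#' @param c Width (log-CFU units, > 0).
#' @param rms Optional RMS residual recorded by [fit_calibration()].
#' @return An object of class `calibration_map`.
#' @examples
#' cal <- calibration_map(a = 4.00, b = 0.884, c = 3.064)
#' @export
calibration_map <- function(a, b, c, rms = NULL) {
  assert_number(a, "a")
  assert_number(b, "b")
  assert_number(c, "c")
  if (a <= 0 || c <= 0) abort("`a` and `c` must be positive")
  structure(list(a = a, b = b, c = c, rms = rms), class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map> y = %g * tanh((x - %g) / %g)%s\n",
              x$a, x$b, x$c,
              if (is.null(x$rms)) "" else sprintf("  [RMS %.4g]", x$rms)))
  invisible(x)
}

#' Tidy a calibration map
#' @param x A `calibration_map`.
#' @param ... Unused.
#' @export
tidy.calibration_map <- function(x, ...) {
  out <- tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
  se <- attr(x, "std_error")
  if (!is.null(se)) out$std.error <- se
  out
}

#' Forward and inverse calibration transforms
#'
#' `logcfu_to_loggfp()` applies y = a tanh((x - b)/c); it is strictly
#' increasing and bounded in (-a, a). `loggfp_to_logcfu()` applies the exact
#' inverse x = (c/2) ln((1 + y/a)/(1 - y/a)) + b, defined for |y| < a.
#' Measured fluorescence can exceed the fitted asymptote, so by default
#' out-of-domain y is clipped to +/- (a - 1e-9) with a warning.
#'
#' @param x Log10 CFU values (finite).
#' @param y Log10 GFP values.
#' @param map A [calibration_map()].
#' @param clip Clip `y` into the open domain instead of erroring.
#' @return Transformed values.
#' @examples
#' m <- calibration_map(4, 0.884, 3.064)
#' loggfp_to_logcfu(logcfu_to_loggfp(3, m), m)
#' @export
logcfu_to_loggfp <- function(x, map) {
  stopifnot(inherits(map, "calibration_map"))
  if (any(!is.finite(x))) abort("`x` must be finite")
  map$a * tanh((x - map$b) / map$c)
}

#' @rdname logcfu_to_loggfp
#' @export
loggfp_to_logcfu <- function(y, map, clip = TRUE) {
  stopifnot(inherits(map, "calibration_map"))
  out_of_domain <- abs(y) >= map$a
  if (any(out_of_domain)) {
    if (!clip) {
      abort(sprintf("|y| >= a for %d value(s); the inverse map is undefined there",
                    sum(out_of_domain)))
    }
    warn(sprintf("clipping %d value(s) of |y| >= a into the inverse-map domain",
                 sum(out_of_domain)))
    y <- pmin(pmax(y, -(map$a - 1e-9)), map$a - 1e-9)
  }
  (map$c / 2) * log((1 + y / map$a) / (1 - y / map$a)) + map$b
}

#' Fit the calibration map by nonlinear least squares
#'
#' Fits y = a tanh((x - b)/c) to paired (log10 CFU, log10 GFP) measurements
#' in the forward direction with uniform weights, via the
#' Levenberg-Marquardt routine in \pkg{minpack.lm}. An identifiability
#' diagnostic flags fits whose data never approach saturation (wide
#' confidence on `a`).
#'
#' @param pairs Data frame with columns `log_cfu` and `log_gfp` (>= 4 rows
#'   spanning both the linear and saturating regime).
#' @return A [calibration_map()] carrying `rms`, per-parameter standard
#'   errors (`std_error` attribute) and `poorly_identified` flag.
#' @export
fit_calibration <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("log_cfu", "log_gfp") %in% names(pairs))) {
    abort("`pairs` must be a data frame with columns log_cfu, log_gfp")
  }
  pairs <- pairs[complete.cases(pairs[, c("log_cfu", "log_gfp")]), ]
  if (nrow(pairs) < 4) abort("need >= 4 calibration pairs")
  start <- list(a = max(abs(pairs$log_gfp)) * 1.05 + 0.1,
                b = pairs$log_cfu[which.min(abs(pairs$log_gfp))],
                c = diff(range(pairs$log_cfu)) / 2 + 0.5)
  resid_fn <- function(par) {
    pairs$log_gfp - par[["a"]] * tanh((pairs$log_cfu - par[["b"]]) / par[["c"]])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(unlist(start), fn = resid_fn,
                       lower = c(a = 1e-6, b = -Inf, c = 1e-6),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("calibration fit failed to converge: ",
                                     conditionMessage(e)))
  )
  if (fit$info == 0 || fit$info == 9) {
    abort(sprintf("calibration fit failed to converge: %s", fit$message))
  }
  est <- coef(fit)
  # standard errors from the Jacobian; singular when a is unconstrained by
  # the data (no saturation in the design)
  se <- tryCatch({
    covm <- solve(fit$hessian) * fit$deviance / (nrow(pairs) - 3)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 3))
  rms <- sqrt(mean(fit$fvec^2))
  out <- calibration_map(est[["a"]], est[["b"]], est[["c"]], rms = rms)
  attr(out, "std_error") <- unname(se)
  # relative uncertainty on the asymptote blows up when x never nears b + 2c
  attr(out, "poorly_identified") <- is.na(se[1]) || se[1] / est[["a"]] > 0.25
  out
}

#' Change of variables for densities under the calibration map
#'
#' Transforms a probability density on log10 CFU into the corresponding
#' density on log10 GFP: P(y) = P(x(y)) (c/a) / (1 - (y/a)^2). Mass at loads
#' far above the center piles up toward the asymptote, producing the
#' left-skew compression seen in fluorescence histograms.
#'
#' @param density_x A function: density on log-CFU (integrating to 1).
#' @param map A [calibration_map()].
#' @return A function giving the density on log-GFP, supported on (-a, a).
#' @export
transform_density <- function(density_x, map) {
  stopifnot(is.function(density_x), inherits(map, "calibration_map"))
  function(y) {
    out <- numeric(length(y))
    ok <- abs(y) < map$a
    if (any(ok)) {
      x <- loggfp_to_logcfu(y[ok], map, clip = FALSE)
      out[ok] <- density_x(x) * (map$c / map$a) / (1 - (y[ok] / map$a)^2)
    }
    out
  }
}

#' @importFrom stats residuals
NULL
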