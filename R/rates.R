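#' Per-isolate colonization/birth/death rates
#'
#' Container for the parameters of the stochastic logistic null model of gut
#' colonization: bacteria colonize empty gut sites from the environment at
#' rate `c` (per empty site), divide into empty sites at rate `b`, and die at
#' rate `d`, with total occupancy capped by the carrying capacity `V`.
#'
#' @param b Birth (within-host division) rate, 1/h. Nonnegative.
#' @param c Colonization (immigration) rate per empty site, 1/h. Nonnegative.
#' @param d Death/loss rate, 1/h. Nonnegative.
#' @param V Carrying capacity of the gut, cells. Positive integer.
#'
#' @return An object of class `logistic_rates`.
#' @examples
#' logistic_rates(b = 1, c = 0.05, d = 0.2, V = 1000)
#' @export
logistic_rates <- function(b, c, d, V) {
  assert_number(b, "b", lower = 0)
  assert_number(c, "c", lower = 0)
  assert_number(d, "d", lower = 0)
  assert_number(V, "V", lower = 1)
  if (V != round(V)) abort("`V` must be a whole number of cells")
  structure(list(b = b, c = c, d = d, V = as.integer(round(V))),
            class = "logistic_rates")
}

#' @export
print.logistic_rates <- function(x, ...) {
  cat(sprintf(
    "<logistic_rates> b = %g /h, c = %g /h, d = %g /h, V = %d cells (b - d = %g /h)\n",
    x$b, x$c, x$d, x$V, x$b - x$d))
  invisible(x)
}

#' @export
as_tibble.logistic_rates <- function(x, ...) {
  tibble(b = x$b, c = x$c, d = x$d, V = x$V)
}

#' Serialize rates to/from flat JSON records
#'
#' @param rates A [logistic_rates()] object (optionally carrying fit
#'   diagnostics as attributes).
#' @param path File path to write to / read from.
#' @return `write_rates_json()` returns `path` invisibly; `read_rates_json()`
#'   returns a [logistic_rates()] object.
#' @export
write_rates_json <- function(rates, path) {
  stopifnot(inherits(rates, "logistic_rates"))
  rec <- list(b = rates$b, c = rates$c, d = rates$d, V = rates$V)
  rec$residual <- attr(rates, "residual")
  rec$n_points <- attr(rates, "n_points")
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rates_json
#' @export
read_rates_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- logistic_rates(rec$b, rec$c, rec$d, rec$V)
  attr(out, "residual") <- rec$residual
  attr(out, "n_points") <- rec$n_points
  out
}
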