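# Internal helpers shared across modules.

# One master seed; per-unit substreams are derived once up front so that
# ensembles are reproducible regardless of how the per-worm loop is ordered.
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

# Truncated-normal draws by rejection: values < 0 are redrawn, not clipped,
# so the rate distributions carry no atom at zero.
rtrunc_normal <- function(n, mean, sd) {
  if (sd < 0) abort("`sd` must be nonnegative")
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

assert_snapshot <- function(x, name = "snapshot") {
  need <- c("worm_id", "time_h", "load", "condition")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns %s",
                  name, paste(need, collapse = ", ")))
  }
  if (any(x$load < 0, na.rm = TRUE)) abort("snapshot loads must be nonnegative")
  invisible(x)
}
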