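# Shared fixtures: a colonizer whose growth phase spans the sampling window,
# the two-state model at the field-typical log-load states, and a symmetric
# double well for closed-form checks.

fix_rates <- function() logistic_rates(b = 0.4, c = 0.005, d = 0.1, V = 1000)

fix_times <- function() c(3, 12, 18, 24, 36, 42, 48)

fix_switching <- function() {
  switching_model(r_low = 1, C_low = 2, D_low = 0.2,
                  r_high = 1, C_high = 5.5, D_high = 0.2,
                  alpha_h = 0.08, alpha_l = 0.02)
}

# U = (phi^2 - 1)^2 / 4: minima at +/-1 (K = 2), barrier at 0 (K = 1),
# barrier height 1/4.
double_well <- function(D) poly_potential(c(0.25, 0, -0.5, 0, 0.25), D = D)

make_snapshot <- function(times, loads, n_per_time = NULL, condition = "x") {
  if (is.null(n_per_time)) n_per_time <- length(loads) / length(times)
  tibble::tibble(
    worm_id = sprintf("w%03d", rep(seq_len(n_per_time), times = length(times))),
    time_h = rep(times, each = n_per_time),
    load = loads,
    condition = condition
  )
}
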