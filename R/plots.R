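#' Plot a snapshot of per-worm loads over time
#'
#' Log10 load (zeros shown at the detection floor) per worm against time,
#' with the per-time mean of positive loads overlaid.
#'
#' @param snapshot Snapshot data frame.
#' @param floor Display floor for zero loads.
#' @return A ggplot object.
#' @export
plot_snapshot <- function(snapshot, floor = 1) {
  assert_snapshot(snapshot)
  df <- dplyr::mutate(snapshot, log_load = log10(pmax(.data$load, floor)))
  means <- dplyr::summarise(
    dplyr::group_by(df, .data$time_h, .data$condition),
    log_mean = log10(pmax(mean(.data$load), floor)), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$log_load)) +
    ggplot2::geom_jitter(width = 0.5, height = 0, alpha = 0.4, size = 1) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(y = .data$log_mean),
                        color = "blue", size = 3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (h)", y = "log10 load")
}

#' @export
autoplot.gmm2 <- function(object, xlim = NULL, ...) {
  xlim <- xlim %||% (range(object$mu) + c(-4, 4) * max(object$sigma))
  grid <- seq(xlim[1], xlim[2], length.out = 400)
  df <- tibble(phi = grid, density = gmm_pdf(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 load", y = "density",
                  title = "Two-component mixture density")
}

#' @export
autoplot.occupancy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$p_high)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (h)", y = "P(high state)")
}

#' @export
autoplot.switching_fit <- function(object, ...) {
  df <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_high)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_fitted), color = "blue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (h)", y = "P(high state)",
                  subtitle = sprintf("alpha_h = %.3g /h, alpha_l = %.3g /h",
                                     object$alpha_h, object$alpha_l))
}

#' @export
autoplot.effective_potential <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$phi, y = .data$R)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$count), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "log10 load", y = "R = -ln density")
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "poly_potential"))
    grid <- seq(min(object$phi), max(object$phi), length.out = 300)
    p <- p + ggplot2::geom_line(
      data = tibble(phi = grid, R = potential_value(fit, grid)),
      ggplot2::aes(x = .data$phi, y = .data$R), color = "blue")
  }
  p
}

#' @export
autoplot.poly_potential <- function(object, support = NULL, ...) {
  support <- support %||% attr(object, "support") %||% c(-2, 8)
  grid <- seq(support[1], support[2], length.out = 400)
  df <- tibble(phi = grid, U = potential_value(object, grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$U)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 load",
                  y = if (object$scale == "R") "R(phi)" else "U(phi)")
}
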