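# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy the crossing table of a Hopf report
#'
#' @param x A `hopf_report`.
#' @param ... Unused.
#' @return Tibble of candidate crossings: `omega` (rad/ms), `T` (ms), `loop`,
#'   `j`, `f_hz`.
#' @export
tidy.hopf_report <- function(x, ...) {
  cr <- tibble::as_tibble(x$crossings)
  dplyr::mutate(cr, f_hz = 1000 * .data$omega / (2 * pi))
}

#' One-row summary of a Hopf report
#'
#' @param x A `hopf_report`.
#' @param ... Unused.
#' @return One-row tibble: `T0`, `omega0`, `f0_hz`, `loop0`, verdicts `H1`,
#'   `H2`, `H3`, `hopf`, `re_lambda_prime`, and (when computed) `mu2`,
#'   `beta2`, `T2` and the classification labels.
#' @export
glance.hopf_report <- function(x, ...) {
  out <- tibble::tibble(
    T0 = x$T0, omega0 = x$omega0, f0_hz = x$f0_hz, loop0 = x$loop0,
    H1 = x$H1, H2 = x$H2, H3 = x$H3, hopf = x$hopf,
    re_lambda_prime = if (x$H1) Re(x$transversality$lambda_prime) else NA_real_)
  if (!is.null(x$normal_form)) {
    nf <- x$normal_form
    out <- dplyr::bind_cols(out, tibble::tibble(
      mu2 = nf$mu2, beta2 = nf$beta2, T2 = nf$T2,
      direction = nf$direction, orbit_stability = nf$orbit_stability,
      period_trend = nf$period_trend))
  }
  out
}

#' @export
tidy.bg_normal_form <- function(x, ...) {
  tibble::tibble(
    term = c("g20", "g11", "g02", "g21", "c1", "mu2", "beta2", "T2"),
    real = c(Re(x$g20), Re(x$g11), Re(x$g02), Re(x$g21), Re(x$c1),
             x$mu2, x$beta2, x$T2),
    imaginary = c(Im(x$g20), Im(x$g11), Im(x$g02), Im(x$g21), Im(x$c1), 0, 0, 0))
}

#' Plot a simulated firing-rate trace
#'
#' @param object A `bg_trace` from [simulate_bg()].
#' @param populations Which series to draw.
#' @param ... Unused.
#' @return A ggplot object: firing rate vs time, one line per population.
#' @export
autoplot.bg_trace <- function(object, populations = c("S", "G", "E", "I"), ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("t", populations)],
                              -"t", names_to = "population", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$rate, colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "firing rate (spk/s)") +
    ggplot2::theme_minimal()
}

#' Plot a one-parameter bifurcation diagram
#'
#' Draws the post-transient extrema of the STN rate against the scanned
#' parameter (fixed points collapse onto a single curve) with the analytic
#' onset overlaid when available.
#'
#' @param object A `bg_scan` from [ramp_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bg_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$S_min, linetype = .data$direction)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$S_max, linetype = .data$direction)) +
    ggplot2::labs(x = unique(d$param), y = "S extrema (spk/s)") +
    ggplot2::theme_minimal()
  ac <- attr(object, "analytic_critical")
  if (length(ac) && is.finite(ac)) {
    gg <- gg + ggplot2::geom_vline(xintercept = ac, linetype = "dashed")
  }
  gg
}

#' Plot a codimension-two stability map
#'
#' @param object A `bg_map` from [hopf_boundary_2d()].
#' @param ... Unused.
#' @return A ggplot object: band label per cell, boundary points overlaid.
#' @export
autoplot.bg_map <- function(object, ...) {
  axes <- attr(object, "axes")
  d <- tibble::as_tibble(object)
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$band)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = axes[["x"]], y = axes[["y"]]) +
    ggplot2::theme_minimal()
  b <- attr(object, "boundary")
  if (!is.null(b) && nrow(b)) {
    gg <- gg + ggplot2::geom_point(data = b, ggplot2::aes(.data$x, .data$y),
                                   inherit.aes = FALSE, size = 0.4)
  }
  gg
}
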