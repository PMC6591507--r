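#' Plot a time-resolved curve
#'
#' @param object A `tpsf_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tpsf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ps, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "intensity (arb.)") +
    ggplot2::theme_minimal()
}

#' Plot a fit: measurement, best-fit simulated curve, fitting range
#'
#' @param object An `op_fit` from [fit_optical_properties()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.op_fit <- function(object, ...) {
  rng_t <- object$measured$time_ps[object$fit_range]
  df <- dplyr::bind_rows(
    dplyr::mutate(object$measured, curve = "measured"),
    dplyr::mutate(object$best_curve, curve = "best fit"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ps, .data$intensity,
                                   colour = .data$curve,
                                   linetype = .data$curve)) +
    ggplot2::annotate("rect", xmin = rng_t[1], xmax = rng_t[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (ps)", y = "normalized intensity",
      title = sprintf("mua = %g mm^-1, musp = %g mm^-1 (RMSE %.4f)",
                      object$best_mua, object$best_musp, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a depth-contribution profile
#'
#' @param object A `depth_profile` from [depth_contribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_profile <- function(object, ...) {
  win <- attr(object, "time_window")
  lab <- ifelse(is.finite(object$depth_hi),
                sprintf("%g-%g", object$depth_lo, object$depth_hi),
                sprintf(">%g", object$depth_lo))
  df <- dplyr::mutate(object, depth_bin = factor(lab, levels = lab))
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_bin, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "maximum depth below fiber tips (mm)",
                  y = "fraction of detected weight",
                  title = sprintf("arrival window %g-%g ps", win[1], win[2])) +
    ggplot2::theme_minimal()
}

#' Plot a slice of a look-up table
#'
#' Draws the peak-normalized TPSFs of one musp column over a set of
#' absorption values.
#'
#' @param lut A `tpsf_lut`.
#' @param musp A musp grid value.
#' @param mua_values Absorption grid values to draw (defaults to ~5 spread
#'   over the grid).
#' @param t_max_ps Right edge of the time axis shown.
#' @return A ggplot.
#' @export
plot_lut_slice <- function(lut, musp, mua_values = NULL, t_max_ps = 150) {
  if (is.null(mua_values)) {
    k <- unique(round(seq(1, length(lut$mua_values), length.out = 5)))
    mua_values <- lut$mua_values[k]
  }
  df <- purrr::map_dfr(mua_values, function(a)
    dplyr::mutate(lut_cell(lut, musp, a), mua = a))
  ggplot2::ggplot(dplyr::filter(df, .data$time_ps <= t_max_ps),
                  ggplot2::aes(.data$time_ps, .data$intensity,
                               colour = factor(.data$mua))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "normalized intensity",
                  colour = "mua (mm^-1)",
                  title = sprintf("musp = %g mm^-1", musp)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
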