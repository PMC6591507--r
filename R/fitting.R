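#' Convolve a TPSF with the instrument response function
#'
#' Discrete linear convolution of the simulated TPSF with the IRF,
#' truncated to the TPSF's time axis and then peak-normalized -- the shape
#' that is compared against a peak-normalized measurement.  Both curves
#' must share the bin width; the IRF's absolute time origin contributes a
#' fixed delay that the fit's registration search absorbs.
#'
#' @param tpsf A TPSF curve (any data frame with `time_ps`, `intensity`).
#' @param irf The IRF curve on the same bin width.
#' @param normalize Peak-normalize the result (default) or return the raw
#'   convolution (linear in the input).
#' @return A `tpsf_curve` on the TPSF's time grid.
#' @export
convolve_irf <- function(tpsf, irf, normalize = TRUE) {
  tpsf <- as_curve(tpsf)
  irf <- as_curve(irf)
  bw <- bin_width_of(tpsf)
  if (abs(bin_width_of(irf) - bw) > 1e-6 * bw)
    abort("`tpsf` and `irf` must share the same bin width")
  y <- conv_truncated(tpsf$intensity, irf$intensity)
  out <- new_curve(tpsf$time_ps, y)
  if (normalize) peak_normalize(out) else out
}

# linear convolution, first length(x) terms: y[k] = sum_j x[j] h[k - j + 1]
conv_truncated <- function(x, h) {
  nx <- length(x)
  nf <- 2^ceiling(log2(nx + length(h) - 1))
  xf <- stats::fft(c(x, numeric(nf - nx)))
  hf <- stats::fft(c(h, numeric(nf - length(h))))
  y <- Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(nx)] / nf
  pmax(y, 0)
}

# convolve many TPSF rows (matrix cells x bins) with one IRF kernel
conv_rows_truncated <- function(mat, h) {
  nx <- ncol(mat)
  nf <- 2^ceiling(log2(nx + length(h) - 1))
  pad <- matrix(0, nrow = nf, ncol = nrow(mat))
  pad[seq_len(nx), ] <- t(mat)
  hf <- stats::fft(c(h, numeric(nf - length(h))))
  y <- Re(stats::mvfft(stats::mvfft(pad) * hf, inverse = TRUE))[seq_len(nx), , drop = FALSE] / nf
  t(pmax(y, 0))
}

#' Fraction-of-peak fitting range
#'
#' For a peak-normalized curve, returns the contiguous closed bin range
#' containing the peak that extends to the last bin >= `leading_fraction`
#' walking back from the peak and to the last bin >= `falling_fraction`
#' walking forward -- the "10/10" or "40/40" range depending on the
#' fractions.  Crossings are evaluated at bin resolution (no sub-bin
#' interpolation).
#'
#' @param curve A peak-normalized curve.
#' @param leading_fraction,falling_fraction Fractions of the peak in (0, 1).
#' @return Integer vector `c(first, last)` of 1-based bin indices.
#' @export
fit_range <- function(curve, leading_fraction = 0.1, falling_fraction = 0.1) {
  curve <- as_curve(curve)
  if (leading_fraction <= 0 || leading_fraction >= 1 ||
      falling_fraction <= 0 || falling_fraction >= 1)
    abort("fractions must lie strictly between 0 and 1")
  if (!is_peak_normalized(curve, tol = 1e-6))
    abort("`curve` must be peak-normalized (max intensity 1)")
  y <- curve$intensity
  ipk <- which.max(y)
  first <- ipk
  while (first > 1 && y[first - 1] >= leading_fraction) first <- first - 1
  last <- ipk
  while (last < length(y) && y[last + 1] >= falling_fraction) last <- last + 1
  c(first = first, last = last)
}

#' Root mean square error over a bin range
#'
#' `sqrt(mean((measured - simulated)^2))` over the closed bin range, the
#' objective minimised by the LUT grid search.
#'
#' @param measured,simulated Curves on identical time grids (or bare
#'   numeric vectors of equal length).
#' @param range Integer `c(first, last)`, 1-based.
#' @export
rmse_in_range <- function(measured, simulated, range) {
  m <- if (is.numeric(measured)) measured else as_curve(measured)$intensity
  s <- if (is.numeric(simulated)) simulated else as_curve(simulated)$intensity
  if (length(m) != length(s)) abort("curves differ in length")
  range <- as.integer(range)
  if (length(range) != 2 || range[1] > range[2] || range[1] < 1 ||
      range[2] > length(m))
    abort("`range` must be a valid non-empty bin range")
  idx <- range[1]:range[2]
  sqrt(mean((m[idx] - s[idx])^2))
}

#' Estimate optical properties by LUT grid search
#'
#' Exhaustively searches every (musp, mua) cell of the look-up table: the
#' cell's TPSF is convolved with the IRF, peak-normalized, registered to
#' the measurement by an integer bin-shift search, and scored by the RMSE
#' against the peak-normalized measurement over the fraction-of-peak range
#' derived from the measured curve.  The best-fit cell (minimum RMSE; ties
#' broken toward smaller mua, then smaller musp) is returned together with
#' the full RMSE landscape.  The fit is invariant to the overall intensity
#' scale of the measurement.
#'
#' @param measured Measured curve on the LUT's binning (intensities in any
#'   units; normalized internally).
#' @param irf IRF curve on the same bin width; `NULL` fits without IRF
#'   convolution.
#' @param lut A [build_lut()] result.
#' @param config A [fit_config()].
#' @return An object of class `op_fit` with elements `best_mua`,
#'   `best_musp`, `rmse`, `fit_range`, `shift_bins`, `accepted`, the
#'   per-cell landscape `landscape` (tibble), and the aligned best-fit
#'   curve `best_curve`.
#' @export
fit_optical_properties <- function(measured, irf, lut, config = fit_config()) {
  stopifnot(inherits(lut, "tpsf_lut"))
  if (!inherits(config, "fit_config")) abort("`config` must be a fit_config()")
  measured <- as_curve(measured)
  if (nrow(measured) != lut$n_bins)
    abort("`measured` must share the LUT's time binning")
  bw <- bin_width_of(measured)
  if (abs(bw - lut$bin_width) > 1e-6 * lut$bin_width)
    abort("`measured` must share the LUT's bin width")
  meas <- peak_normalize(measured)$intensity

  n_musp <- length(lut$musp_values)
  n_mua <- length(lut$mua_values)
  n_bins <- lut$n_bins
  # cells x bins, mua varying fastest (matches the landscape row order)
  cells <- t(matrix(aperm(lut$tpsf, c(3, 2, 1)), nrow = n_bins))
  if (!is.null(irf)) {
    irf <- as_curve(irf)
    if (abs(bin_width_of(irf) - lut$bin_width) > 1e-6 * lut$bin_width)
      abort("`irf` must share the LUT's bin width")
    cells <- conv_rows_truncated(cells, irf$intensity)
  }
  cells <- cells / apply(cells, 1, max)

  rng <- fit_range(new_curve(measured$time_ps, meas),
                   config$leading_fraction, config$falling_fraction)
  idx <- rng[1]:rng[2]
  target <- meas[idx]

  shifts <- -config$shift_search_halfwidth:config$shift_search_halfwidth
  n_cell <- nrow(cells)
  best_rmse <- rep(Inf, n_cell)
  best_shift <- integer(n_cell)
  padded <- cbind(matrix(0, n_cell, config$shift_search_halfwidth + 1), cells,
                  matrix(0, n_cell, config$shift_search_halfwidth + 1))
  off <- config$shift_search_halfwidth + 1
  for (s in shifts) {
    block <- padded[, idx - s + off, drop = FALSE]
    r <- sqrt(rowMeans((block - rep(target, each = n_cell))^2))
    upd <- r < best_rmse
    best_rmse[upd] <- r[upd]
    best_shift[upd] <- s
  }

  grid <- tidyr::expand_grid(musp = lut$musp_values, mua = lut$mua_values)
  landscape <- dplyr::mutate(grid, rmse = best_rmse, shift_bins = best_shift)
  ord <- order(landscape$rmse, landscape$mua, landscape$musp)
  top <- landscape[ord[1], ]

  i <- match_grid(top$musp, lut$musp_values, "musp")
  j <- match_grid(top$mua, lut$mua_values, "mua")
  cell_row <- (i - 1) * n_mua + j
  aligned <- shift_bins(cells[cell_row, ], top$shift_bins)
  structure(list(best_mua = top$mua, best_musp = top$musp,
                 rmse = top$rmse, shift_bins = top$shift_bins,
                 fit_range = rng,
                 accepted = top$rmse < config$rmse_threshold,
                 rmse_threshold = config$rmse_threshold,
                 landscape = landscape,
                 measured = new_curve(measured$time_ps, meas),
                 best_curve = new_curve(measured$time_ps, aligned),
                 config = config,
                 lut_meta = list(musp_range = range(lut$musp_values),
                                 mua_range = range(lut$mua_values),
                                 bin_width = lut$bin_width, g = lut$g,
                                 n = lut$n)),
            class = "op_fit")
}

# shift a vector by s bins (positive = later), zero-filled
shift_bins <- function(x, s) {
  n <- length(x)
  if (s == 0) return(x)
  if (s > 0) c(numeric(s), x[seq_len(n - s)])
  else c(x[(1 - s):n], numeric(-s))
}

#' @export
print.op_fit <- function(x, ...) {
  cat(sprintf("<op_fit> mua = %g mm^-1, musp = %g mm^-1\n",
              x$best_mua, x$best_musp))
  cat(sprintf("  RMSE %.5f over bins %d..%d (%.1f..%.1f ps), shift %+d bins, %s\n",
              x$rmse, x$fit_range[1], x$fit_range[2],
              x$measured$time_ps[x$fit_range[1]],
              x$measured$time_ps[x$fit_range[2]],
              x$shift_bins,
              if (x$accepted) sprintf("accepted (< %g)", x$rmse_threshold)
              else sprintf("NOT accepted (>= %g)", x$rmse_threshold)))
  invisible(x)
}

#' @export
tidy.op_fit <- function(x, ...) {
  tibble::tibble(term = c("mua", "musp"),
                 estimate = c(x$best_mua, x$best_musp),
                 unit = "mm^-1")
}

#' @export
glance.op_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, accepted = x$accepted,
                 shift_bins = x$shift_bins,
                 fit_start_ps = x$measured$time_ps[x$fit_range[1]],
                 fit_end_ps = x$measured$time_ps[x$fit_range[2]],
                 n_cells = nrow(x$landscape))
}
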