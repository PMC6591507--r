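#' Synthesize an instrument response function
#'
#' A unit-peak Gaussian of the requested FWHM sampled on the bin grid,
#' optionally with a secondary Gaussian "hump" on the falling edge -- the
#' shape seen when a reflection inside the streak camera trails the main
#' response.  The main peak is centred a few sigma into the support so the
#' leading tail is fully represented.
#'
#' @param fwhm Full width at half maximum, ps (> 0).
#' @param bin_width Bin width, ps.
#' @param hump Optional `list(delay, amplitude, width)`: a secondary
#'   Gaussian `amplitude` (< 1, relative to the main peak) centred `delay`
#'   ps after the main peak with FWHM `width` ps.
#' @return A `tpsf_curve` tibble of class `irf` with unit peak.
#' @export
#' @examples
#' irf <- synthesize_irf(fwhm = 3.44)
#' measure_fwhm(irf)
synthesize_irf <- function(fwhm = 3.44, bin_width = 0.3125, hump = NULL) {
  stopifnot(fwhm > 0, bin_width > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  hump_delay <- 0
  hump_sigma <- 0
  if (!is.null(hump)) {
    hump <- modifyList(list(delay = 10, amplitude = 0.2, width = fwhm), hump)
    if (hump$amplitude >= 1)
      abort("hump `amplitude` must stay below 1 (a secondary feature)")
    stopifnot(hump$delay > 0, hump$width > 0)
    hump_delay <- hump$delay
    hump_sigma <- hump$width / (2 * sqrt(2 * log(2)))
  }
  t0 <- (ceiling(6 * sigma / bin_width) + 0.5) * bin_width
  t_end <- t0 + hump_delay + 6 * max(sigma, hump_sigma)
  n <- ceiling(t_end / bin_width)
  t <- bin_centers(n, bin_width)
  y <- exp(-(t - t0)^2 / (2 * sigma^2))
  if (!is.null(hump))
    y <- y + hump$amplitude * exp(-(t - t0 - hump_delay)^2 / (2 * hump_sigma^2))
  out <- peak_normalize(new_curve(t, y))
  class(out) <- c("irf", class(out))
  out
}

# Smoothing-spline estimate of the underlying (infinite-budget) TPSF:
# log intensity against sqrt(time) -- the root axis concentrates knots at
# the early, highly curved part of the decay.  Bins outside the occupied
# support stay zero.
smooth_tpsf <- function(curve, df = 45) {
  v <- curve$intensity
  pos <- which(v > 0)
  if (length(pos) < df + 4) return(curve)
  i0 <- min(pos); i1 <- max(pos)
  idx <- i0:i1
  vv <- v[idx]
  floor_v <- max(vv) * 1e-7
  fit <- stats::smooth.spline(sqrt(curve$time_ps[idx]), log(pmax(vv, floor_v)),
                              w = sqrt(pmax(vv, floor_v)), df = df)
  out <- v
  out[idx] <- exp(stats::predict(fit, sqrt(curve$time_ps[idx]))$y)
  new_curve(curve$time_ps, out)
}

# a single-bin unit impulse on the given binning
impulse_irf <- function(bin_width = 0.3125) {
  out <- new_curve(bin_centers(2, bin_width), c(1, 0))
  class(out) <- c("irf", class(out))
  out
}

apply_noise <- function(values, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$mode == "none") return(values)
  out <- withr::with_seed(noise$seed, {
    if (noise$mode == "shot") {
      tot <- sum(values)
      if (tot <= 0) abort("cannot add shot noise to an all-zero curve")
      counts <- rpois(length(values), values / tot * noise$scale)
      counts * tot / noise$scale
    } else {
      values + rnorm(length(values), sd = noise$scale * max(values))
    }
  })
  pmax(out, 0)
}

#' Generate a synthetic time-resolved measurement
#'
#' Emulates a streak-camera TPSF measurement for a medium with known
#' optical properties: a white Monte Carlo run at the medium's scattering
#' properties, Beer-Lambert rescaling to its `mua`, convolution with the
#' IRF, an embedded integer bin shift (arbitrary trigger offset), noise,
#' and peak normalization.
#'
#' @param props [optical_properties()] of the medium (`mua` >= 0 here --
#'   it is applied by rescaling, not simulated).
#' @param probe A [probe_geometry()].
#' @param irf An IRF curve, or `NULL` for an ideal impulse response.
#' @param noise A [noise_model()].
#' @param shift_bins Integer time shift embedded in the output, bins.
#' @param config A [sim_config()] for the underlying white run.
#' @param white Optionally a precomputed [run_white_mc()] result at the
#'   same scattering properties, to reuse across `mua` values or noise
#'   draws.
#' @param smooth_df If non-`NULL`, the Monte Carlo TPSF is replaced by a
#'   smoothing-spline estimate (this many effective degrees of freedom, on
#'   a square-root time axis, in log intensity) before convolution and
#'   noise.  A physical measurement integrates billions of laser pulses,
#'   so its pre-shot-noise curve is smooth; the spline projection emulates
#'   that by removing the residual Monte Carlo noise of the finite photon
#'   budget.  `NULL` (default) uses the raw binned curve.
#' @return A peak-normalized `tpsf_curve`; the white run used is attached
#'   as attribute `white_run`.
#' @export
forward_measurement <- function(props, probe = probe_geometry(), irf = NULL,
                                noise = noise_model("none"), shift_bins = 0L,
                                config = sim_config(), white = NULL,
                                smooth_df = NULL) {
  stopifnot(inherits(props, "optical_properties"))
  if (is.null(white)) {
    white <- run_white_mc(optical_properties(0, props$mus, props$g, props$n),
                          probe, config)
  } else {
    fp <- white$config_fingerprint
    if (!isTRUE(all.equal(c(fp$mus, fp$g, fp$n), c(props$mus, props$g, props$n))))
      abort("`white` was simulated at different scattering properties")
  }
  tpsf <- rescale_to_mua(white, props$mua)
  if (!is.null(smooth_df)) tpsf <- smooth_tpsf(tpsf, df = smooth_df)
  cv <- if (is.null(irf)) tpsf else convolve_irf(tpsf, irf, normalize = FALSE)
  vals <- shift_bins(cv$intensity, as.integer(shift_bins))
  vals <- apply_noise(vals, noise)
  if (max(vals) <= 0) abort("noise produced an all-zero curve")
  out <- peak_normalize(new_curve(tpsf$time_ps, vals))
  attr(out, "white_run") <- white
  out
}

#' Measurement scenario presets
#'
#' Tabulated optical properties and probe configurations for round-trip
#' experiments: a latex/dye liquid phantom (mua 0.0231 mm^-1, mus 15.6
#' mm^-1, g 0.836 at 800 nm, fibers immersed 0.5 mm; liquid refractive
#' index taken as 1.33), single-measurement examples of rat gray matter
#' (mua 0.052, musp 1.70) and monkey gray matter (mua 0.081, musp 1.8),
#' and cohort-mean gray/white-matter values for rat and monkey.  Tissue
#' presets use g = 0.9 and n = 1.4.
#'
#' @param name One of `"phantom"`, `"rat_gray"`, `"rat_white"`,
#'   `"monkey_gray"`, `"monkey_white"`, `"fig3a_rat"`, `"fig3b_monkey"`.
#' @return A `scenario_preset`: list with `name`, `props`
#'   ([optical_properties()]), `probe` ([probe_geometry()]) and `expected`
#'   (named vector of the mua and musp a round-trip fit should recover).
#' @export
#' @examples
#' preset("rat_gray")$props
preset <- function(name) {
  tissue <- function(mua, musp)
    optical_properties_musp(mua, musp, g = 0.9, n = 1.4)
  entry <- switch(
    name,
    phantom = list(props = optical_properties(0.0231, 15.6, 0.836, 1.33),
                   probe = probe_geometry(immersion_depth = 0.5)),
    rat_gray = list(props = tissue(0.054, 1.67)),
    rat_white = list(props = tissue(0.029, 2.13)),
    monkey_gray = list(props = tissue(0.084, 1.97)),
    monkey_white = list(props = tissue(0.021, 2.40)),
    fig3a_rat = list(props = tissue(0.052, 1.70)),
    fig3b_monkey = list(props = tissue(0.081, 1.8)),
    abort(sprintf("unknown preset \"%s\"", name)))
  probe <- entry$probe %||% probe_geometry()
  structure(list(name = name, props = entry$props, probe = probe,
                 expected = c(mua = entry$props$mua,
                              musp = entry$props$musp)),
            class = "scenario_preset")
}

preset_names <- function() {
  c("phantom", "rat_gray", "rat_white", "monkey_gray", "monkey_white",
    "fig3a_rat", "fig3b_monkey")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("<scenario_preset> %s: mua = %g, musp = %g mm^-1 (g = %g, n = %g)\n",
              x$name, x$props$mua, x$props$musp, x$props$g, x$props$n))
  invisible(x)
}
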