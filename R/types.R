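#' Optical properties of a homogeneous turbid medium
#'
#' Bundles the four quantities that determine photon transport in a
#' homogeneous medium: the absorption coefficient `mua` (mm^-1), the
#' scattering coefficient `mus` (mm^-1), the scattering anisotropy `g`
#' (mean cosine of the single-scattering polar angle) and the refractive
#' index `n`.  The reduced scattering coefficient `musp = mus * (1 - g)`
#' is derived and stored alongside.
#'
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param mus Scattering coefficient, mm^-1 (> 0).
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index (>= 1).
#' @return An object of class `optical_properties`.
#' @seealso [optical_properties_musp()] to parameterise by `musp` instead.
#' @export
#' @examples
#' optical_properties(mua = 0.052, mus = 17, g = 0.9, n = 1.4)
optical_properties <- function(mua, mus, g, n) {
  stopifnot(is.numeric(mua), length(mua) == 1, is.finite(mua),
            is.numeric(mus), length(mus) == 1, is.finite(mus),
            is.numeric(g), length(g) == 1, is.finite(g),
            is.numeric(n), length(n) == 1, is.finite(n))
  if (mua < 0) abort("`mua` must be >= 0")
  if (mus <= 0) abort("`mus` must be > 0")
  if (abs(g) >= 1) abort("`g` must lie strictly between -1 and 1")
  if (n < 1) abort("`n` must be >= 1")
  structure(list(mua = mua, mus = mus, g = g, n = n, musp = mus * (1 - g)),
            class = "optical_properties")
}

#' @rdname optical_properties
#' @param musp Reduced scattering coefficient, mm^-1 (> 0); `mus` is derived
#'   as `musp / (1 - g)`.
#' @export
optical_properties_musp <- function(mua, musp, g, n) {
  stopifnot(is.numeric(musp), length(musp) == 1, musp > 0)
  optical_properties(mua = mua, mus = musp / (1 - g), g = g, n = n)
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties> mua = %g mm^-1, mus = %g mm^-1 (musp = %g), g = %g, n = %g\n",
    x$mua, x$mus, x$musp, x$g, x$n))
  invisible(x)
}

#' Source/detector fiber geometry
#'
#' Describes the two-fiber reflectance probe: a source fiber launching light
#' over a circular spot within a cone, and a detector fiber a fixed distance
#' away accepting light within its numerical aperture.  Defaults reproduce a
#' 50 um core / NA 0.2 fiber pair separated by 1.25 mm, in surface contact
#' with the medium (`immersion_depth = 0`).  A positive `immersion_depth`
#' places the fiber tips that far below the free surface of the medium
#' (liquid-phantom configuration); the free surface then reflects light back
#' into the medium.
#'
#' @param source_radius Source spot radius, mm.
#' @param source_half_angle Launch cone half-angle, degrees, applied in the
#'   medium.
#' @param detector_radius Detector spot radius, mm.
#' @param detector_na Detector numerical aperture (in-air sine of the
#'   acceptance half-angle), in (0, 1).
#' @param separation Centre-to-centre source-detector distance, mm.
#' @param immersion_depth Depth of the fiber tips below the free surface of
#'   the medium, mm; 0 means surface contact.
#' @param n_outside Refractive index of the medium above the interface.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(source_radius = 0.025, source_half_angle = 11.5,
                           detector_radius = 0.025, detector_na = 0.2,
                           separation = 1.25, immersion_depth = 0,
                           n_outside = 1.0) {
  stopifnot(source_radius > 0, detector_radius > 0, separation > 0,
            source_half_angle > 0, source_half_angle < 90,
            immersion_depth >= 0, n_outside >= 1)
  if (detector_na <= 0 || detector_na >= 1)
    abort("`detector_na` must lie strictly between 0 and 1")
  if (separation <= source_radius + detector_radius)
    abort("`separation` must exceed the sum of the fiber spot radii")
  structure(list(source_radius = source_radius,
                 source_half_angle = source_half_angle,
                 detector_radius = detector_radius,
                 detector_na = detector_na,
                 separation = separation,
                 immersion_depth = immersion_depth,
                 n_outside = n_outside),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "<probe_geometry> rho = %g mm, source %g mm / %g deg, detector %g mm / NA %g%s\n",
    x$separation, x$source_radius, x$source_half_angle, x$detector_radius,
    x$detector_na,
    if (x$immersion_depth > 0) sprintf(", immersed %g mm", x$immersion_depth)
    else ", surface contact"))
  invisible(x)
}

#' Simulation configuration for white Monte Carlo runs
#'
#' Time binning, photon budgets, random seed and estimator switches for
#' [run_white_mc()].  The 0.3125 ps bin matches the temporal resolution of a
#' streak camera; 300 ps / 0.3125 ps gives 960 bins.
#'
#' Two detection estimators are available.  `"crossing"` detects a packet
#' when its transmitted exit position and angle meet the fiber acceptance --
#' the analog reference.  `"escape"` (default) credits, at every scattering
#' vertex near the surface, the expected packet weight escaping straight into
#' the detection cone onto the detector (last-scattering-vertex estimator,
#' `k_cone` directional samples per vertex), which reaches a given variance
#' orders of magnitude faster.  Both estimators can use the `"ring"` detector
#' (an annulus at the source-detector distance, exploiting the azimuthal
#' symmetry of the half-space problem, reweighted by the spot/annulus area
#' ratio) or the literal `"spot"`.  `n_split` > 1 additionally splits each
#' photon the first time it enters the region near the detector.
#'
#' @param bin_width Time bin width, ps.
#' @param t_max Time-of-flight cutoff, ps; must be an integer multiple of
#'   `bin_width`.
#' @param n_detected Stop after this many detected records (optional).
#' @param n_launched Stop after launching this many photon packets
#'   (optional; at least one of the two budgets must be given).
#' @param seed Integer seed for the simulation's random stream.
#' @param detector `"ring"` or `"spot"`.
#' @param estimator `"escape"` or `"crossing"`.
#' @param n_split Hot-zone splitting multiplicity (1 disables splitting).
#' @param k_cone Directional samples per escape-estimator evaluation.
#' @param n_branch One-step branching multiplicity near the detector: the
#'   escape credit of each next vertex is averaged over this many virtual
#'   scatter-and-fly continuations before the walk adopts one of them
#'   (1 disables branching).
#' @param max_records Stored records above this count are compressed by
#'   unbiased weight roulette (0 disables).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(bin_width = 0.3125, t_max = 300,
                       n_detected = NULL, n_launched = NULL,
                       seed = 1L, detector = c("ring", "spot"),
                       estimator = c("escape", "crossing"),
                       n_split = 10L, k_cone = 4L, n_branch = 16L,
                       max_records = 3e5) {
  detector <- match.arg(detector)
  estimator <- match.arg(estimator)
  stopifnot(bin_width > 0, t_max > 0, n_split >= 1, k_cone >= 1,
            n_branch >= 1, max_records >= 0)
  n_bins <- t_max / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9)
    abort("`t_max` must be an integer multiple of `bin_width`")
  if (is.null(n_detected) && is.null(n_launched))
    abort("give at least one of `n_detected` or `n_launched`")
  if (!is.null(n_detected) && n_detected <= 0)
    abort("`n_detected` must be a positive count")
  if (!is.null(n_launched) && n_launched <= 0)
    abort("`n_launched` must be a positive count")
  structure(list(bin_width = bin_width, t_max = t_max,
                 n_bins = as.integer(round(n_bins)),
                 n_detected = n_detected, n_launched = n_launched,
                 seed = as.integer(seed), detector = detector,
                 estimator = estimator, n_split = as.integer(n_split),
                 k_cone = as.integer(k_cone), n_branch = as.integer(n_branch),
                 max_records = max_records),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d bins x %g ps, %s/%s estimator, seed %d%s%s\n",
    x$n_bins, x$bin_width, x$detector, x$estimator, x$seed,
    if (!is.null(x$n_detected)) sprintf(", target %g records", x$n_detected) else "",
    if (!is.null(x$n_launched)) sprintf(", budget %g photons", x$n_launched) else ""))
  invisible(x)
}

#' Fitting configuration
#'
#' Controls the LUT grid-search fit: the fraction-of-peak fitting range on
#' the leading and falling edges (0.1/0.1 by default; 0.4/0.4 avoids
#' falling-edge artefacts such as a humped IRF), the RMSE acceptance
#' threshold and the half-width (in bins) of the integer time-shift
#' registration search between the measured and simulated curves.
#'
#' @param leading_fraction,falling_fraction Fractions of the peak value that
#'   delimit the fitting range, each in (0, 1).
#' @param rmse_threshold A fit is flagged accepted when its minimum RMSE is
#'   below this value.
#' @param shift_search_halfwidth Registration search half-width, bins.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(leading_fraction = 0.1, falling_fraction = 0.1,
                       rmse_threshold = 0.025, shift_search_halfwidth = 16L) {
  stopifnot(leading_fraction > 0, leading_fraction < 1,
            falling_fraction > 0, falling_fraction < 1,
            rmse_threshold > 0, shift_search_halfwidth >= 0)
  structure(list(leading_fraction = leading_fraction,
                 falling_fraction = falling_fraction,
                 rmse_threshold = rmse_threshold,
                 shift_search_halfwidth = as.integer(shift_search_halfwidth)),
            class = "fit_config")
}

#' Noise model for synthetic measurements
#'
#' `"shot"` rescales the noiseless curve to `scale` total counts and draws
#' Poisson counts per bin (streak-camera photon statistics); `"gaussian"`
#' adds zero-mean Gaussian noise with standard deviation `scale` times the
#' peak; `"none"` leaves the curve untouched.  Negative values are clipped
#' at zero.
#'
#' @param mode `"none"`, `"shot"` or `"gaussian"`.
#' @param scale Total counts (shot) or relative standard deviation
#'   (gaussian).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(mode = c("none", "shot", "gaussian"), scale = NULL,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (mode != "none") {
    if (is.null(scale) || !is.numeric(scale) || scale <= 0)
      abort(sprintf("`scale` must be a positive number for mode \"%s\"", mode))
  }
  structure(list(mode = mode, scale = scale, seed = as.integer(seed)),
            class = "noise_model")
}
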