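#' Sample the Henyey-Greenstein polar scattering cosine
#'
#' Closed-form inverse-CDF sampling of the Henyey-Greenstein phase function:
#' given a uniform variate u in \[0, 1), returns the cosine of the polar
#' scattering angle.  At g = 0 this reduces to the isotropic cos(theta) =
#' 2u - 1; the expectation of the returned cosine equals g.  The azimuthal
#' angle is uniform and sampled separately by the transport kernel.
#'
#' @param g Scattering anisotropy, strictly inside (-1, 1).
#' @param u Uniform variates in \[0, 1) (vectorised).
#' @return Cosines in \[-1, 1\].
#' @export
#' @examples
#' hg_sample(0.9, 0.5)
hg_sample <- function(g, u) {
  stopifnot(is.numeric(g), length(g) == 1)
  if (abs(g) >= 1) abort("`g` must lie strictly between -1 and 1")
  if (any(u < 0 | u >= 1)) abort("`u` must lie in [0, 1)")
  hg_cos_cpp(g, as.numeric(u))
}

#' Exponential free path length
#'
#' The distance to the next scattering event, `-log(u) / mus`, exponentially
#' distributed with mean `1/mus`.  `u = 0` is rejected (it would give an
#' infinite step); `u = 1` gives a zero-length step.
#'
#' @param mus Scattering coefficient, mm^-1 (> 0).
#' @param u Uniform variates in (0, 1\] (vectorised).
#' @return Path lengths in mm.
#' @export
step_length <- function(mus, u) {
  stopifnot(is.numeric(mus), length(mus) == 1, mus > 0)
  if (any(u <= 0 | u > 1)) abort("`u` must lie in (0, 1]")
  -log(u) / mus
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel power reflectances for light
#' incident from refractive index `n1` onto `n2`.  Returns 1 beyond the
#' critical angle when `n1 > n2`; symmetric under swapping `n1` and `n2` at
#' normal incidence.
#'
#' @param n1,n2 Refractive indices on the incidence and transmission sides.
#' @param cos_incident Cosine of the incidence angle, in \[0, 1\]
#'   (vectorised).
#' @return Reflectances in \[0, 1\].
#' @export
fresnel_unpolarized <- function(n1, n2, cos_incident) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (any(cos_incident < 0 | cos_incident > 1))
    abort("`cos_incident` must lie in [0, 1]")
  fresnel_unpolarized_cpp(n1, n2, as.numeric(cos_incident))
}

#' Time of flight from optical path length
#'
#' `t = L * n / c` with c = 0.299792458 mm/ps.
#'
#' @param path_length Geometric path length in the medium, mm (>= 0).
#' @param n Refractive index of the medium.
#' @return Time in ps.
#' @export
time_of_flight <- function(path_length, n) {
  if (any(path_length < 0)) abort("`path_length` must be >= 0")
  path_length * n / c_mm_ps()
}

#' Fiber detection condition
#'
#' Tests whether an exit position and exit polar angle meet the detector
#' fiber's acceptance: the exit point must lie within the detector spot
#' (centred `separation` away from the source along x) and the sine of the
#' exit polar angle in the outside medium must not exceed the numerical
#' aperture.  This is the analog ("crossing") detection rule; the transport
#' kernel applies the identical test.
#'
#' @param x,y Exit coordinates in the fiber-tip plane, mm (vectorised).
#' @param sin_exit Sine of the exit polar angle in the outside medium.
#' @param probe A [probe_geometry()].
#' @param mode `"spot"` tests the literal detector area; `"ring"` tests the
#'   annulus at the source-detector distance.
#' @return Logical vector.
#' @export
detect_check <- function(x, y, sin_exit, probe, mode = c("spot", "ring")) {
  mode <- match.arg(mode)
  in_angle <- sin_exit <= probe$detector_na
  if (mode == "spot") {
    in_area <- (x - probe$separation)^2 + y^2 <= probe$detector_radius^2
  } else {
    r <- sqrt(x^2 + y^2)
    in_area <- r >= probe$separation - probe$detector_radius &
      r <= probe$separation + probe$detector_radius
  }
  in_area & in_angle
}

#' Run a white (zero-absorption) Monte Carlo simulation
#'
#' Simulates photon-packet transport in a semi-infinite homogeneous medium
#' at `mua = 0` and returns per-detected-packet records: estimator weight,
#' total optical path length, number of scattering events, deepest point
#' reached (measured from the fiber-tip plane) and arrival time bin.
#' Because the medium is absorption-free, the records can later be
#' reweighted to any absorption coefficient by Beer-Lambert's
#' `exp(-mua * path_length)` (see [rescale_to_mua()]) -- the "white Monte
#' Carlo" device that makes the absorption axis of a look-up table free.
#'
#' Packets terminate by escaping through the interface, by exceeding the
#' time-of-flight cutoff, or as soon as the detection region is no longer
#' reachable within the remaining path budget (tallied as truncated).
#' See [sim_config()] for the detection estimators and variance-reduction
#' switches.
#'
#' @param medium An [optical_properties()] with `mua = 0` (nonzero `mua` is
#'   rejected -- absorption belongs to the rescaling step).
#' @param probe A [probe_geometry()].
#' @param config A [sim_config()].
#' @return An object of class `white_run`: list with `records` (tibble),
#'   the weight tallies `launched_weight`, `detected_weight`,
#'   `escaped_weight`, `truncated_weight`, the effective sample size `ess`
#'   of the detected weights, and `config_fingerprint` (provenance).
#' @export
run_white_mc <- function(medium, probe = probe_geometry(), config = sim_config()) {
  stopifnot(inherits(medium, "optical_properties"),
            inherits(probe, "probe_geometry"),
            inherits(config, "sim_config"))
  if (medium$mua != 0)
    abort("white Monte Carlo requires `mua = 0`; apply absorption with rescale_to_mua()")
  if (probe$detector_na >= medium$n)
    abort("`detector_na` must be smaller than the medium refractive index")
  res <- mc_white_run_cpp(
    mus = medium$mus, g = medium$g, n_in = medium$n, n_out = probe$n_outside,
    src_radius = probe$source_radius,
    src_half_angle_deg = probe$source_half_angle,
    det_radius = probe$detector_radius, det_na = probe$detector_na,
    rho = probe$separation, immersion_depth = probe$immersion_depth,
    bin_width_ps = config$bin_width, t_max_ps = config$t_max,
    n_launched_max = config$n_launched %||% -1,
    n_detected_target = config$n_detected %||% -1,
    seed = config$seed,
    ring = config$detector == "ring",
    escape_estimator = config$estimator == "escape",
    n_split = config$n_split, k_cone = config$k_cone,
    n_branch = config$n_branch,
    max_records = config$max_records, rho_scales = 1.0)
  records <- tibble::tibble(weight = res$weight,
                            path_length = res$path_length,
                            n_scatter = res$n_scatter,
                            max_depth = res$max_depth,
                            arrival_bin = res$arrival_bin)
  if (nrow(records) == 0)
    warning("no packets were detected; increase the photon budget")
  fingerprint <- white_fingerprint(medium, probe, config)
  structure(list(records = records,
                 n_launched = res$n_launched,
                 launched_weight = res$launched_weight,
                 detected_weight = res$detected_weight,
                 escaped_weight = res$escaped_weight,
                 truncated_weight = res$truncated_weight,
                 rouletted_weight = res$rouletted_weight,
                 n_records_raw = res$n_records_raw,
                 ess = res$ess,
                 config_fingerprint = fingerprint),
            class = "white_run")
}

white_fingerprint <- function(medium, probe, config) {
  list(mus = medium$mus, g = medium$g, n = medium$n, musp = medium$musp,
       probe = unclass(probe),
       bin_width = config$bin_width, t_max = config$t_max,
       n_bins = config$n_bins, seed = config$seed,
       detector = config$detector, estimator = config$estimator,
       n_split = config$n_split, k_cone = config$k_cone,
       n_branch = config$n_branch,
       package_version = as.character(packageVersion("tpsfit")))
}

#' White runs for several reduced scattering values from one walk ensemble
#'
#' With the anisotropy fixed, a photon walk at scattering coefficient `mus`
#' evaluated against a detector annulus scaled by `k = mus_target / mus` is
#' an exact realisation of the medium with `mus_target` and the unscaled
#' detector: free path lengths scale as `1/mus` while every angular and
#' Fresnel draw coincides (similarity scaling).  This function therefore
#' runs a single simulation at the largest requested `musp` and evaluates
#' the detection estimator against one scaled annulus per `musp` value,
#' returning a list of `white_run` objects whose records are expressed in
#' each target's own units.  The runs are perfectly correlated across the
#' `musp` axis -- differences between neighbouring look-up-table columns
#' built from them are physical, not statistical -- and the full photon
#' budget benefits every column.  The one approximation is the source spot,
#' whose 25 um radius is not rescaled (against a 1.25 mm separation).
#'
#' Only surface-contact geometries are supported (an immersion depth does
#' not obey the similarity scaling).
#'
#' @param musp_values Reduced scattering coefficients, mm^-1.
#' @param g,n Anisotropy and refractive index.
#' @param probe A [probe_geometry()] with `immersion_depth = 0`.
#' @param config A [sim_config()]; `n_launched` sets the shared budget.
#' @return A list of `white_run` objects, one per `musp` value, in input
#'   order.
#' @export
run_white_mc_scaled <- function(musp_values, g = 0.9, n = 1.4,
                                probe = probe_geometry(),
                                config = sim_config()) {
  stopifnot(length(musp_values) >= 1, all(musp_values > 0))
  if (probe$immersion_depth > 0)
    abort("similarity-scaled runs require surface contact (immersion_depth = 0)")
  if (is.null(config$n_launched))
    abort("scaled runs need an `n_launched` budget")
  musp_ref <- max(musp_values)
  medium_ref <- optical_properties_musp(0, musp_ref, g, n)
  scales <- musp_values / musp_ref
  res <- mc_white_run_cpp(
    mus = medium_ref$mus, g = g, n_in = n, n_out = probe$n_outside,
    src_radius = probe$source_radius,
    src_half_angle_deg = probe$source_half_angle,
    det_radius = probe$detector_radius, det_na = probe$detector_na,
    rho = probe$separation, immersion_depth = 0,
    bin_width_ps = config$bin_width, t_max_ps = config$t_max,
    n_launched_max = config$n_launched, n_detected_target = -1,
    seed = config$seed,
    ring = config$detector == "ring",
    escape_estimator = config$estimator == "escape",
    n_split = config$n_split, k_cone = config$k_cone,
    n_branch = config$n_branch,
    max_records = config$max_records, rho_scales = scales)
  all_records <- tibble::tibble(weight = res$weight,
                                path_length = res$path_length,
                                n_scatter = res$n_scatter,
                                max_depth = res$max_depth,
                                arrival_bin = res$arrival_bin,
                                target = res$target)
  purrr::map(seq_along(musp_values), function(j) {
    medium_j <- optical_properties_musp(0, musp_values[j], g, n)
    fingerprint <- white_fingerprint(medium_j, probe, config)
    fingerprint$scaled_from_musp <- musp_ref
    structure(list(records = dplyr::select(
                     dplyr::filter(all_records, .data$target == j - 1L),
                     -"target"),
                   n_launched = res$n_launched,
                   launched_weight = res$launched_weight,
                   detected_weight = res$detected_weight,
                   escaped_weight = res$escaped_weight,
                   truncated_weight = res$truncated_weight,
                   rouletted_weight = res$rouletted_weight,
                   n_records_raw = res$n_records_raw,
                   ess = res$ess[j],
                   config_fingerprint = fingerprint),
              class = "white_run")
  })
}

#' @export
print.white_run <- function(x, ...) {
  fp <- x$config_fingerprint
  cat(sprintf(
    "<white_run> musp = %g mm^-1 (g = %g, n = %g), rho = %g mm\n",
    fp$musp, fp$g, fp$n, fp$probe$separation))
  cat(sprintf(
    "  %g photons launched, %d records kept (%.0f raw, ESS %.0f), %s/%s\n",
    x$n_launched, nrow(x$records), x$n_records_raw, x$ess,
    fp$detector, fp$estimator))
  invisible(x)
}

#' @export
tidy.white_run <- function(x, ...) x$records

#' @export
glance.white_run <- function(x, ...) {
  tibble::tibble(n_launched = x$n_launched,
                 n_records = nrow(x$records),
                 ess = x$ess,
                 detected_weight = x$detected_weight,
                 escaped_weight = x$escaped_weight,
                 truncated_weight = x$truncated_weight,
                 musp = x$config_fingerprint$musp,
                 seed = x$config_fingerprint$seed)
}

#' Serialize white runs
#'
#' Writes/reads a [run_white_mc()] result to a schema-versioned JSON
#' container holding the per-record arrays and the full provenance
#' fingerprint; `white_run_load(white_run_save(x))` reproduces every array
#' bit-exactly.
#'
#' @param run A `white_run`.
#' @param path File path (conventionally `.json`).
#' @export
white_run_save <- function(run, path) {
  stopifnot(inherits(run, "white_run"))
  payload <- list(schema = "tpsfit/white_run/1",
                  records = as.list(run$records),
                  n_launched = run$n_launched,
                  launched_weight = run$launched_weight,
                  detected_weight = run$detected_weight,
                  escaped_weight = run$escaped_weight,
                  truncated_weight = run$truncated_weight,
                  rouletted_weight = run$rouletted_weight %||% 0,
                  n_records_raw = run$n_records_raw,
                  ess = run$ess,
                  config_fingerprint = run$config_fingerprint)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname white_run_save
#' @export
white_run_load <- function(path) {
  if (!file.exists(path)) abort(sprintf("white-run file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "tpsfit/white_run/1"))
    abort(sprintf("unrecognised white-run schema in %s: %s",
                  path, p$schema %||% "<missing>"))
  rec <- p$records
  structure(list(records = tibble::tibble(weight = as.numeric(rec$weight),
                                          path_length = as.numeric(rec$path_length),
                                          n_scatter = as.integer(rec$n_scatter),
                                          max_depth = as.numeric(rec$max_depth),
                                          arrival_bin = as.integer(rec$arrival_bin)),
                 n_launched = p$n_launched,
                 launched_weight = p$launched_weight,
                 detected_weight = p$detected_weight,
                 escaped_weight = p$escaped_weight,
                 truncated_weight = p$truncated_weight,
                 rouletted_weight = p$rouletted_weight %||% 0,
                 n_records_raw = p$n_records_raw,
                 ess = p$ess,
                 config_fingerprint = p$config_fingerprint),
            class = "white_run")
}
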