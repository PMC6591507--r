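# Shared fixtures. Monte Carlo fixtures use a deliberately "fat" probe
# (wide detector, high NA, short separation) and a coarser medium so that
# detection is frequent and runs take seconds; the physics exercised is
# identical to the production geometry.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

fat_probe <- function(...) {
  probe_geometry(detector_radius = 0.3, detector_na = 0.5,
                 separation = 1.0, ...)
}

fat_medium <- function(mua = 0, mus = 5, g = 0.7, n = 1.4) {
  optical_properties(mua, mus, g, n)
}

fat_run <- function() {
  cached("fat_run", run_white_mc(
    fat_medium(), fat_probe(),
    sim_config(n_launched = 3e4, seed = 42)))
}

fat_run_crossing <- function() {
  cached("fat_run_crossing", run_white_mc(
    fat_medium(), fat_probe(),
    sim_config(n_launched = 1.5e5, seed = 43,
               estimator = "crossing", n_split = 1)))
}

# coarse time rebinning of a curve's intensities, normalized to fractions
coarse_fractions <- function(values, factor = 64) {
  n <- floor(length(values) / factor)
  x <- vapply(seq_len(n), function(k)
    sum(values[((k - 1) * factor + 1):(k * factor)]), numeric(1))
  x / sum(x)
}

# analytic look-up table built from diffusion-theory curves: smooth,
# deterministic, instant -- used to exercise the fitting machinery
# independently of any Monte Carlo run
diffusion_lut <- function(musp_values = seq(1.0, 3.0, by = 0.25),
                          mua_values = seq(0.01, 0.09, by = 0.005),
                          n = 1.4, rho = 1.25,
                          bin_width = 0.3125, t_max = 300) {
  n_bins <- round(t_max / bin_width)
  times <- ((seq_len(n_bins)) - 0.5) * bin_width
  tpsf <- array(0, dim = c(length(musp_values), length(mua_values), n_bins))
  for (i in seq_along(musp_values)) for (j in seq_along(mua_values)) {
    v <- diffusion_tpsf(mua_values[j], musp_values[i], n, rho, times)$intensity
    tpsf[i, j, ] <- v / max(v)
  }
  structure(list(musp_values = musp_values, mua_values = mua_values,
                 tpsf = tpsf, bin_width = bin_width, t_max = t_max,
                 n_bins = n_bins, g = 0.9, n = n,
                 meta = list(probe = unclass(probe_geometry()),
                             seeds = integer(length(musp_values)),
                             estimator = "analytic", detector = "none",
                             ess = rep(Inf, length(musp_values)),
                             package_version = "test")),
            class = "tpsf_lut")
}

# hand-built white run for analytic record-level tests
fake_white_run <- function(weight, path_length, max_depth = NULL,
                           bin_width = 0.3125, t_max = 300,
                           n = 1.4, musp = 1.7, g = 0.9) {
  arrival_bin <- as.integer(floor(path_length * n / 0.299792458 / bin_width))
  records <- tibble::tibble(
    weight = weight, path_length = path_length,
    n_scatter = rep(3L, length(weight)),
    max_depth = max_depth %||% rep(0.5, length(weight)),
    arrival_bin = arrival_bin)
  structure(list(records = records, n_launched = length(weight),
                 launched_weight = length(weight),
                 detected_weight = sum(weight), escaped_weight = 0,
                 truncated_weight = 0, n_records_raw = length(weight),
                 ess = length(weight),
                 config_fingerprint = list(
                   mus = musp / (1 - g), g = g, n = n, musp = musp,
                   probe = unclass(probe_geometry()),
                   bin_width = bin_width, t_max = t_max,
                   n_bins = as.integer(round(t_max / bin_width)),
                   seed = 0L, detector = "ring", estimator = "escape",
                   n_split = 1L, k_cone = 1L,
                   package_version = "test")),
            class = "white_run")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
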