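#' Apply absorption to a white run by Beer-Lambert reweighting
#'
#' Each detected record of a zero-absorption run contributes
#' `weight * exp(-mua * path_length)` to its arrival bin -- the white
#' Monte Carlo identity that turns one simulation into a TPSF for any
#' absorption coefficient.  At `mua = 0` the raw white accumulation is
#' returned unchanged.
#'
#' @param white A [run_white_mc()] result.
#' @param mua Absorption coefficient, mm^-1 (>= 0).
#' @param normalize Peak-normalize the result?
#' @return A `tpsf_curve` tibble on the run's time grid.
#' @export
rescale_to_mua <- function(white, mua, normalize = FALSE) {
  stopifnot(inherits(white, "white_run"))
  if (!is.numeric(mua) || length(mua) != 1 || mua < 0)
    abort("`mua` must be a single non-negative number")
  fp <- white$config_fingerprint
  vals <- bin_accumulate(white$records$weight * exp(-mua * white$records$path_length),
                         white$records$arrival_bin, fp$n_bins)
  cv <- new_curve(bin_centers(fp$n_bins, fp$bin_width), vals)
  if (normalize) peak_normalize(cv) else cv
}

# weighted bin counts for 0-based bins
bin_accumulate <- function(w, bin, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(w, bin, reorder = TRUE)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  out
}

#' Look-up-table grid
#'
#' The (musp, mua) grid over which the LUT holds one peak-normalized TPSF
#' per cell.  Defaults cover 0.6 to 4.0 mm^-1 in steps of 0.1 for musp and
#' 0 to 0.1 mm^-1 in steps of 0.001 for mua.  Only the musp axis costs
#' Monte Carlo runs; the mua axis is generated by rescaling.
#'
#' @param musp_values Strictly increasing reduced scattering grid, mm^-1.
#' @param mua_values Strictly increasing absorption grid, mm^-1 (0 allowed).
#' @return An object of class `lut_grid`.
#' @export
lut_grid <- function(musp_values = seq(0.6, 4.0, by = 0.1),
                     mua_values = seq(0, 0.1, by = 0.001)) {
  musp_values <- as.numeric(musp_values)
  mua_values <- as.numeric(mua_values)
  if (any(diff(musp_values) <= 0) || any(diff(mua_values) <= 0))
    abort("grid values must be strictly increasing")
  if (any(musp_values <= 0)) abort("`musp_values` must be positive")
  if (any(mua_values < 0)) abort("`mua_values` must be non-negative")
  structure(list(musp_values = musp_values, mua_values = mua_values),
            class = "lut_grid")
}

#' Build a TPSF look-up table from white runs
#'
#' Expands one white run per reduced-scattering value into a grid of
#' peak-normalized TPSFs over all (musp, mua) combinations via Beer-Lambert
#' rescaling, so the table costs exactly `length(musp_values)` Monte Carlo
#' runs regardless of the absorption grid.  All runs must share binning and
#' probe geometry; each run's musp (from its provenance fingerprint) must
#' match the grid.
#'
#' @param white_runs List of [run_white_mc()] results, one per musp grid
#'   value, in grid order.
#' @param mua_values Absorption grid, mm^-1.
#' @return An object of class `tpsf_lut`: the grid, a 3-D array
#'   `tpsf[musp, mua, bin]` of peak-normalized TPSFs, binning and
#'   provenance metadata.
#' @seealso [simulate_lut()] to run the simulations and build in one call.
#' @export
build_lut <- function(white_runs, mua_values = seq(0, 0.1, by = 0.001)) {
  if (!length(white_runs) || !all(vapply(white_runs, inherits, logical(1), "white_run")))
    abort("`white_runs` must be a non-empty list of white_run objects")
  mua_values <- lut_grid(mua_values = mua_values,
                         musp_values = vapply(white_runs, function(r)
                           r$config_fingerprint$musp, numeric(1)))$mua_values
  musp_values <- vapply(white_runs, function(r) r$config_fingerprint$musp,
                        numeric(1))
  if (any(diff(musp_values) <= 0))
    abort("`white_runs` must be ordered by strictly increasing musp")
  fp0 <- white_runs[[1]]$config_fingerprint
  for (r in white_runs) {
    fp <- r$config_fingerprint
    same <- isTRUE(all.equal(fp$bin_width, fp0$bin_width)) &&
      identical(fp$n_bins, fp0$n_bins) &&
      isTRUE(all.equal(fp$probe, fp0$probe)) &&
      isTRUE(all.equal(fp$g, fp0$g)) && isTRUE(all.equal(fp$n, fp0$n))
    if (!same)
      abort("white runs disagree in binning, probe geometry, g or n")
  }
  n_bins <- fp0$n_bins
  tpsf <- array(0, dim = c(length(musp_values), length(mua_values), n_bins))
  for (i in seq_along(white_runs)) {
    rec <- white_runs[[i]]$records
    if (nrow(rec) == 0) abort(sprintf("white run %d holds no records", i))
    for (j in seq_along(mua_values)) {
      v <- bin_accumulate(rec$weight * exp(-mua_values[j] * rec$path_length),
                          rec$arrival_bin, n_bins)
      tpsf[i, j, ] <- v / max(v)
    }
  }
  structure(list(musp_values = musp_values, mua_values = mua_values,
                 tpsf = tpsf, bin_width = fp0$bin_width, t_max = fp0$t_max,
                 n_bins = n_bins, g = fp0$g, n = fp0$n,
                 meta = list(probe = fp0$probe,
                             seeds = vapply(white_runs, function(r)
                               r$config_fingerprint$seed, integer(1)),
                             estimator = fp0$estimator,
                             detector = fp0$detector,
                             ess = vapply(white_runs, function(r)
                               as.numeric(r$ess), numeric(1)),
                             package_version = fp0$package_version)),
            class = "tpsf_lut")
}

#' Simulate white runs over a musp grid and build the LUT
#'
#' Convenience wrapper: one [run_white_mc()] per `musp` value (the
#' scattering coefficient fed to the simulation is `musp / (1 - g)`),
#' followed by [build_lut()].  By default every run uses the same seed:
#' with a fixed anisotropy, same-seed walks at different scattering
#' coefficients are exact spatial rescalings of one another (free paths
#' scale as 1/mus while all angular draws coincide), so neighbouring LUT
#' columns share their Monte Carlo noise and their differences are almost
#' purely physical -- the common-random-numbers device.  Set
#' `common_seed = FALSE` to give run i seed `config$seed + i - 1`.
#'
#' @inheritParams build_lut
#' @param musp_values Reduced scattering grid, mm^-1.
#' @param g,n Anisotropy and refractive index shared by all runs.
#' @param probe A [probe_geometry()].
#' @param config A [sim_config()]; its seed seeds the first run.
#' @param keep_runs Also return the white runs (`$white_runs`)?
#' @param common_seed Reuse one seed across the musp axis (see Details)?
#' @param method `"scaled"` evaluates all musp values from one walk
#'   ensemble by similarity scaling ([run_white_mc_scaled()]; surface
#'   geometries only), so the whole photon budget benefits every column
#'   and the columns are perfectly correlated.  `"independent"` runs one
#'   simulation per musp value.
#' @export
simulate_lut <- function(musp_values, mua_values = seq(0, 0.1, by = 0.001),
                         g = 0.9, n = 1.4, probe = probe_geometry(),
                         config = sim_config(), keep_runs = FALSE,
                         common_seed = TRUE,
                         method = c("scaled", "independent")) {
  method <- match.arg(method)
  if (method == "scaled" && probe$immersion_depth > 0) method <- "independent"
  if (method == "scaled") {
    runs <- run_white_mc_scaled(musp_values, g, n, probe, config)
  } else {
    runs <- purrr::map(seq_along(musp_values), function(i) {
      cfg <- config
      if (!common_seed) cfg$seed <- config$seed + i - 1L
      run_white_mc(optical_properties_musp(0, musp_values[i], g, n), probe, cfg)
    })
  }
  lut <- build_lut(runs, mua_values)
  if (keep_runs) lut$white_runs <- runs
  lut
}

#' @export
print.tpsf_lut <- function(x, ...) {
  cat(sprintf(
    "<tpsf_lut> %d musp x %d mua cells (%d MC runs), %d bins x %g ps\n",
    length(x$musp_values), length(x$mua_values), length(x$musp_values),
    x$n_bins, x$bin_width))
  cat(sprintf("  musp %g..%g, mua %g..%g mm^-1, g = %g, n = %g\n",
              min(x$musp_values), max(x$musp_values),
              min(x$mua_values), max(x$mua_values), x$g, x$n))
  invisible(x)
}

#' Extract one LUT cell as a curve
#' @param lut A `tpsf_lut`.
#' @param musp,mua Grid values (must match grid points exactly).
#' @return A `tpsf_curve` tibble.
#' @export
lut_cell <- function(lut, musp, mua) {
  i <- match_grid(musp, lut$musp_values, "musp")
  j <- match_grid(mua, lut$mua_values, "mua")
  new_curve(bin_centers(lut$n_bins, lut$bin_width), lut$tpsf[i, j, ])
}

match_grid <- function(value, grid, what) {
  i <- which(abs(grid - value) < 1e-9)
  if (length(i) != 1)
    abort(sprintf("%s = %g is not a grid point", what, value))
  i
}

#' @export
tidy.tpsf_lut <- function(x, ...) {
  tidyr::expand_grid(musp = x$musp_values, mua = x$mua_values) |>
    dplyr::mutate(tpsf = purrr::map2(.data$musp, .data$mua,
                                     function(s, a) lut_cell(x, s, a)))
}

#' Serialize a look-up table
#'
#' Writes/reads the LUT to a schema-versioned JSON container with the
#' grids, the flattened TPSF array and the provenance metadata;
#' `lut_load(lut_save(x))` reproduces the grids and every TPSF value
#' bit-exactly.  A container whose binning metadata is inconsistent with
#' the stored array is rejected with the offending field named.
#'
#' @param lut A `tpsf_lut`.
#' @param path File path (conventionally `.json`).
#' @export
lut_save <- function(lut, path) {
  stopifnot(inherits(lut, "tpsf_lut"))
  payload <- list(schema = "tpsfit/lut/1",
                  musp_values = lut$musp_values,
                  mua_values = lut$mua_values,
                  dim = dim(lut$tpsf),
                  tpsf = as.vector(lut$tpsf),
                  bin_width = lut$bin_width, t_max = lut$t_max,
                  n_bins = lut$n_bins, g = lut$g, n = lut$n,
                  meta = lut$meta)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname lut_save
#' @export
lut_load <- function(path) {
  if (!file.exists(path)) abort(sprintf("LUT file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "tpsfit/lut/1"))
    abort(sprintf("unrecognised LUT schema in %s: %s",
                  path, p$schema %||% "<missing>"))
  dm <- as.integer(p$dim)
  if (length(p$tpsf) != prod(dm))
    abort("LUT schema error: field `tpsf` length disagrees with `dim`")
  if (dm[1] != length(p$musp_values))
    abort("LUT schema error: field `musp_values` disagrees with `dim`")
  if (dm[2] != length(p$mua_values))
    abort("LUT schema error: field `mua_values` disagrees with `dim`")
  if (dm[3] != p$n_bins)
    abort("LUT schema error: field `n_bins` disagrees with `dim`")
  nb <- p$t_max / p$bin_width
  if (abs(nb - p$n_bins) > 1e-6)
    abort("LUT schema error: field `bin_width` inconsistent with `t_max`/`n_bins`")
  meta <- p$meta
  meta$seeds <- as.integer(meta$seeds)
  structure(list(musp_values = as.numeric(p$musp_values),
                 mua_values = as.numeric(p$mua_values),
                 tpsf = array(as.numeric(p$tpsf), dim = dm),
                 bin_width = p$bin_width, t_max = p$t_max,
                 n_bins = as.integer(p$n_bins), g = p$g, n = p$n,
                 meta = meta),
            class = "tpsf_lut")
}
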