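#' Time-resolved diffusion-theory reflectance (semi-infinite medium)
#'
#' Closed-form time-domain reflectance of a semi-infinite homogeneous
#' medium under the diffusion approximation with an extrapolated boundary:
#' an isotropic point source at depth `z0 = 1/musp` and its negative image
#' mirrored about the extrapolated plane `zb = 2 A D`, where `D = 1/(3
#' musp)` and the coefficient A is derived from the refractive-index
#' mismatch (Groenhuis polynomial).  The curve is proportional to
#' `t^(-5/2) exp(-rho^2/(4 D v t)) exp(-mua v t)` times the image-source
#' bracket, with `v = c/n`.
#'
#' Valid deep in the diffusive regime (late times, separations of many
#' transport mean free paths); near the source and at early times it is
#' expected to disagree with transport-accurate Monte Carlo -- which is
#' precisely why the LUT is built by Monte Carlo at rho = 1.25 mm.  Used
#' here as an independent late-time oracle.
#'
#' @param mua Absorption coefficient, mm^-1.
#' @param musp Reduced scattering coefficient, mm^-1 (musp >> mua).
#' @param n Refractive index of the medium.
#' @param rho Source-detector separation, mm.
#' @param times Times, ps (> 0).
#' @param n_outside Refractive index above the boundary.
#' @return A `tpsf_curve` tibble on `times` (arbitrary amplitude units).
#' @export
diffusion_tpsf <- function(mua, musp, n, rho, times, n_outside = 1.0) {
  stopifnot(mua >= 0, musp > 0, n >= 1, rho > 0)
  if (any(times <= 0)) abort("`times` must be positive")
  v <- c_mm_ps() / n
  D <- 1 / (3 * musp)
  z0 <- 1 / musp
  A <- boundary_coefficient_A(n / n_outside)
  zb <- 2 * A * D
  arg <- 4 * D * v * times
  refl <- 0.5 * (4 * pi * D * v)^(-3 / 2) * times^(-5 / 2) *
    exp(-mua * v * times - rho^2 / arg) *
    (z0 * exp(-z0^2 / arg) + (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 / arg))
  new_curve(times, refl)
}

# Groenhuis et al. internal-reflection boundary coefficient
boundary_coefficient_A <- function(n_rel) {
  r_d <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + r_d) / (1 - r_d)
}

#' Depth contribution of the detected light
#'
#' Resolves how deep the light contributing to a (time-windowed) TPSF
#' penetrated: the Beer-Lambert-reweighted detected weight of a white run,
#' restricted to arrival times inside `time_window`, is histogrammed by
#' the deepest point each packet reached below the fiber-tip plane
#' (`max_depth`) and normalized to fractions.
#'
#' @param white A [run_white_mc()] result.
#' @param mua Absorption coefficient applied by reweighting, mm^-1.
#' @param time_window `c(start, end)` arrival-time window, ps.
#' @param depth_edges Increasing depth bin edges, mm (use `Inf` to close
#'   the last bin).
#' @return A tibble of class `depth_profile`: `depth_lo`, `depth_hi`,
#'   `weight`, `fraction` (summing to 1), with the window as attribute
#'   `time_window`.
#' @export
depth_contribution <- function(white, mua = 0, time_window = c(0, 85),
                               depth_edges = c(0, 1, 2, 3, Inf)) {
  stopifnot(inherits(white, "white_run"), mua >= 0)
  if (length(time_window) != 2 || time_window[2] <= time_window[1])
    abort("`time_window` must be an increasing pair of times, ps")
  if (length(depth_edges) < 2 || any(diff(depth_edges) <= 0))
    abort("`depth_edges` must be strictly increasing")
  fp <- white$config_fingerprint
  rec <- white$records
  t_arrival <- (rec$arrival_bin + 0.5) * fp$bin_width
  keep <- t_arrival >= time_window[1] & t_arrival < time_window[2]
  if (!any(keep))
    abort("no detected weight arrives inside `time_window`")
  w <- rec$weight[keep] * exp(-mua * rec$path_length[keep])
  cut_idx <- findInterval(rec$max_depth[keep], depth_edges,
                          rightmost.closed = FALSE)
  in_range <- cut_idx >= 1 & cut_idx < length(depth_edges)
  w <- w[in_range]
  cut_idx <- cut_idx[in_range]
  wsum <- vapply(seq_len(length(depth_edges) - 1),
                 function(k) sum(w[cut_idx == k]), numeric(1))
  out <- tibble::tibble(depth_lo = depth_edges[-length(depth_edges)],
                        depth_hi = depth_edges[-1],
                        weight = wsum,
                        fraction = wsum / sum(wsum))
  attr(out, "time_window") <- time_window
  attr(out, "mua") <- mua
  class(out) <- c("depth_profile", class(out))
  out
}

#' Compare a Monte Carlo TPSF's late-time decay with diffusion theory
#'
#' Fits the log-slope of a white run's TPSF (rescaled to `mua`) over a late
#' time window, coarsely rebinned for statistical stability, and compares
#' it with the log-slope of [diffusion_tpsf()] at the same properties.  In
#' the diffusive regime the two slopes agree; the disagreement at early
#' times reproduces the known failure of the diffusion approximation close
#' to the source.
#'
#' @param white A [run_white_mc()] result.
#' @param mua Absorption applied by reweighting, mm^-1.
#' @param window Late-time window `c(start, end)`, ps.
#' @param rebin_ps Coarse bin width for the slope fit, ps.
#' @return A list with `slope_mc`, `slope_diffusion` (1/ps) and
#'   `relative_difference`.
#' @export
diffusion_slope_check <- function(white, mua = 0.02, window = c(100, 250),
                                  rebin_ps = 10) {
  fp <- white$config_fingerprint
  tpsf <- rescale_to_mua(white, mua)
  fac <- round(rebin_ps / fp$bin_width)
  n_coarse <- floor(nrow(tpsf) / fac)
  grp <- rep(seq_len(n_coarse), each = fac)
  y <- vapply(seq_len(n_coarse),
              function(k) sum(tpsf$intensity[grp == k]), numeric(1))
  t <- (seq_len(n_coarse) - 0.5) * fac * fp$bin_width
  keep <- t >= window[1] & t <= window[2] & y > 0
  if (sum(keep) < 4) abort("too few occupied bins in the slope window")
  slope_mc <- unname(coef(lm(log(y[keep]) ~ t[keep]))[2])
  dif <- diffusion_tpsf(mua, fp$musp, fp$n, fp$probe$separation, t[keep],
                        n_outside = fp$probe$n_outside)
  slope_dif <- unname(coef(lm(log(dif$intensity) ~ t[keep]))[2])
  list(slope_mc = slope_mc, slope_diffusion = slope_dif,
       relative_difference = abs(slope_mc - slope_dif) / abs(slope_dif))
}
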