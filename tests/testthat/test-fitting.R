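# IRF convolution, fitting range, RMSE and the LUT grid search.

test_that("convolving with a unit impulse is the identity", {
  tpsf <- new_curve(bin_centers(64, 0.3125), dgamma(1:64, shape = 3))
  irf <- tpsfit:::impulse_irf(0.3125)
  out <- convolve_irf(tpsf, irf)
  expect_equal(out$intensity, peak_normalize(tpsf)$intensity, tolerance = 1e-12)
})

test_that("Gaussian convolved with Gaussian adds FWHMs in quadrature", {
  bw <- 0.3125
  a <- synthesize_irf(fwhm = 3.44, bin_width = bw)
  b <- synthesize_irf(fwhm = 5, bin_width = bw)
  n <- 400
  long <- new_curve(bin_centers(n, bw),
                    c(b$intensity, numeric(n - nrow(b))))
  out <- convolve_irf(long, a)
  expect_equal(measure_fwhm(out), sqrt(3.44^2 + 5^2), tolerance = bw / 2)
})

test_that("convolution is linear before normalization", {
  bw <- 0.3125
  irf <- synthesize_irf(3.44, bw)
  t <- bin_centers(128, bw)
  a <- new_curve(t, exp(-(t - 10)^2))
  b <- new_curve(t, 0.3 * exp(-0.1 * t))
  ab <- new_curve(t, a$intensity + b$intensity)
  expect_equal(convolve_irf(ab, irf, normalize = FALSE)$intensity,
               convolve_irf(a, irf, normalize = FALSE)$intensity +
                 convolve_irf(b, irf, normalize = FALSE)$intensity,
               tolerance = 1e-9)
  bad <- new_curve(bin_centers(16, 0.625), rep(1, 16))
  expect_error(convolve_irf(a, bad), "bin width")
})

test_that("the fraction-of-peak range walks out from the peak", {
  cv <- new_curve(bin_centers(6, 1), c(0.05, 0.2, 0.6, 1.0, 0.5, 0.08))
  expect_equal(unname(fit_range(cv, 0.1, 0.1)), c(2, 5))
  expect_equal(unname(fit_range(cv, 0.4, 0.4)), c(3, 5))
  # vanishing fractions extend to the full contiguous positive support
  expect_equal(unname(fit_range(cv, 1e-9, 1e-9)), c(1, 6))
  expect_error(fit_range(cv, 1, 0.1), "strictly between")
  expect_error(fit_range(new_curve(1:3, c(1, 2, 1)), 0.1, 0.1),
               "peak-normalized")
})

test_that("RMSE over a range matches hand-computed values", {
  expect_equal(rmse_in_range(c(1, 0.5, 0.2), c(1, 0.5, 0.2), c(1, 3)), 0)
  expect_equal(rmse_in_range(c(1, 0), c(0, 1), c(1, 2)), 1)
  expect_equal(rmse_in_range(c(1, 0.5), c(1, 0.3), c(1, 2)), sqrt(0.04 / 2))
  expect_error(rmse_in_range(c(1, 0), c(0, 1), c(2, 1)), "range")
  expect_error(rmse_in_range(c(1, 0), c(0, 1, 2), c(1, 2)), "length")
})

test_that("fitting a cell's own curve recovers that cell exactly", {
  lut <- diffusion_lut()
  irf <- synthesize_irf(3.44)
  target <- convolve_irf(lut_cell(lut, 2.0, 0.05), irf)
  fit <- fit_optical_properties(target, irf, lut)
  expect_equal(fit$best_musp, 2.0)
  expect_equal(fit$best_mua, 0.05)
  expect_lt(fit$rmse, 1e-10)
  expect_equal(fit$shift_bins, 0)
  expect_true(fit$accepted)
})

test_that("the fit is invariant to intensity scaling of the measurement", {
  lut <- diffusion_lut()
  irf <- synthesize_irf(3.44)
  target <- convolve_irf(lut_cell(lut, 1.5, 0.03), irf, normalize = FALSE)
  f1 <- fit_optical_properties(target, irf, lut)
  f2 <- fit_optical_properties(
    new_curve(target$time_ps, target$intensity * 123.4), irf, lut)
  expect_equal(f1$best_musp, f2$best_musp)
  expect_equal(f1$best_mua, f2$best_mua)
  expect_equal(f1$rmse, f2$rmse)
})

test_that("an embedded time shift is found by the registration search", {
  lut <- diffusion_lut()
  irf <- synthesize_irf(3.44)
  base <- convolve_irf(lut_cell(lut, 2.0, 0.05), irf)
  for (s in c(-7L, 0L, 9L)) {
    shifted <- new_curve(base$time_ps, tpsfit:::shift_bins(base$intensity, s))
    fit <- fit_optical_properties(shifted, irf, lut)
    expect_equal(fit$shift_bins, s)
    expect_equal(fit$best_musp, 2.0)
    expect_equal(fit$best_mua, 0.05)
  }
})

test_that("the noiseless RMSE landscape rises away from the optimum", {
  lut <- diffusion_lut()
  irf <- synthesize_irf(3.44)
  target <- convolve_irf(lut_cell(lut, 2.0, 0.05), irf)
  fit <- fit_optical_properties(target, irf, lut)
  land <- fit$landscape
  # along the musp axis at the true mua
  prof <- land$rmse[land$mua == 0.05]
  i0 <- which(lut$musp_values == 2.0)
  expect_true(all(diff(prof[i0:length(prof)][-(1:3)]) >= -1e-9))
  expect_true(all(diff(rev(prof[1:i0])[-(1:3)]) >= -1e-9))
  # along the mua axis at the true musp
  prof2 <- land$rmse[land$musp == 2.0]
  j0 <- which(lut$mua_values == 0.05)
  expect_true(all(diff(prof2[j0:length(prof2)][-(1:3)]) >= -1e-9))
  expect_true(all(diff(rev(prof2[1:j0])[-(1:3)]) >= -1e-9))
})

test_that("grid-search ties break toward smaller mua, then smaller musp", {
  # two identical musp rows -> every cell duplicated across musp
  v <- dgamma(seq_len(960) / 40, shape = 3)
  tpsf <- array(0, dim = c(2, 2, 960))
  for (i in 1:2) for (j in 1:2) tpsf[i, j, ] <- v / max(v)
  lut <- structure(list(musp_values = c(1, 2), mua_values = c(0.01, 0.02),
                        tpsf = tpsf, bin_width = 0.3125, t_max = 300,
                        n_bins = 960L, g = 0.9, n = 1.4,
                        meta = list()), class = "tpsf_lut")
  target <- lut_cell(lut, 1, 0.01)
  fit <- fit_optical_properties(target, NULL, lut)
  expect_equal(fit$best_mua, 0.01)
  expect_equal(fit$best_musp, 1)
})

test_that("fit rejects inconsistent inputs", {
  lut <- diffusion_lut()
  short <- new_curve(bin_centers(10, 0.3125), 1:10)
  expect_error(fit_optical_properties(short, NULL, lut), "binning")
  wrong_bw <- new_curve(bin_centers(960, 0.625), rep(1, 960))
  expect_error(fit_optical_properties(wrong_bw, NULL, lut), "bin width")
})

test_that("tidy and glance summarise a fit", {
  lut <- diffusion_lut()
  target <- lut_cell(lut, 2.0, 0.05)
  fit <- fit_optical_properties(target, NULL, lut)
  td <- tidy(fit)
  expect_equal(td$term, c("mua", "musp"))
  expect_equal(td$estimate, c(0.05, 2.0))
  gl <- glance(fit)
  expect_true(gl$accepted)
  expect_equal(gl$n_cells, length(lut$musp_values) * length(lut$mua_values))
})
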