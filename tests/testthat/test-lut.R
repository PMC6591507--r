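# Absorption rescaling and look-up-table construction.

test_that("rescaling to mua applies Beer-Lambert per record", {
  # single record W0 = 1, L = 10 mm, mua = 0.05 -> exp(-0.5)
  w <- fake_white_run(weight = 1, path_length = 10)
  cv <- rescale_to_mua(w, 0.05)
  expect_equal(sum(cv$intensity), exp(-0.5))
  expect_equal(cv$intensity[w$records$arrival_bin + 1], exp(-0.5))
  # identity at mua = 0
  cv0 <- rescale_to_mua(w, 0)
  expect_equal(sum(cv0$intensity), 1)
  expect_error(rescale_to_mua(w, -0.01), "non-negative")
})

test_that("per-record rescaling agrees with the analytic bin rescaling", {
  # in a homogeneous medium L = t c / n exactly, so bin-level rescaling by
  # exp(-mua c t / n) matches the record-level Eq.-1 sum to within one bin
  # of path discretization: rel. error < exp(mua * c * dt / n) - 1
  w <- fat_run()
  fp <- w$config_fingerprint
  mua <- 0.1
  per_record <- rescale_to_mua(w, mua)$intensity
  white <- rescale_to_mua(w, 0)
  t_bin <- white$time_ps
  analytic <- white$intensity * exp(-mua * 0.299792458 * t_bin / fp$n)
  bound <- exp(mua * 0.299792458 * fp$bin_width / fp$n) - 1
  occupied <- white$intensity > 0
  rel <- abs(per_record - analytic)[occupied] / pmax(analytic[occupied], 1e-300)
  expect_lt(max(rel), bound + 1e-12)
})

test_that("peak normalization scales to unit maximum and is idempotent", {
  expect_equal(peak_normalize(c(2, 4, 1)), c(0.5, 1, 0.25))
  cv <- new_curve(c(0.5, 1.5, 2.5), c(2, 4, 1))
  nn <- peak_normalize(cv)
  expect_equal(nn$intensity, c(0.5, 1, 0.25))
  expect_equal(peak_normalize(nn)$intensity, nn$intensity)
  # scale invariance
  expect_equal(peak_normalize(new_curve(cv$time_ps, cv$intensity * 37.2))$intensity,
               nn$intensity)
  expect_error(peak_normalize(c(0, 0)), "all-zero")
})

test_that("build_lut expands white runs over the absorption axis", {
  runs <- run_white_mc_scaled(c(1.0, 1.5), g = 0.7, n = 1.4,
                              probe = fat_probe(),
                              config = sim_config(n_launched = 2e4, seed = 51))
  mua_values <- c(0, 0.01, 0.05)
  lut <- build_lut(runs, mua_values)
  expect_equal(dim(lut$tpsf), c(2, 3, 960))
  # every TPSF is peak-normalized with max exactly 1
  expect_equal(apply(lut$tpsf, c(1, 2), max), matrix(1, 2, 3))
  # mua = 0 column reproduces the raw white accumulation
  raw <- peak_normalize(rescale_to_mua(runs[[1]], 0))$intensity
  expect_equal(lut$tpsf[1, 1, ], raw)

  # unnormalized bin content strictly decreasing in mua where occupied
  v1 <- rescale_to_mua(runs[[1]], 0.01)$intensity
  v2 <- rescale_to_mua(runs[[1]], 0.05)$intensity
  occ <- v1 > 0
  expect_true(all(v2[occ] < v1[occ]))

  # mean arrival time of the normalized TPSF decreases as mua grows
  # (late bins are suppressed more); oracle: direct weighted mean over the
  # stored records
  rec <- runs[[1]]$records
  mean_t <- vapply(mua_values, function(a) {
    w <- rec$weight * exp(-a * rec$path_length)
    sum(w * rec$path_length) / sum(w) * 1.4 / 0.299792458
  }, numeric(1))
  expect_true(all(diff(mean_t) < 0))
  lut_means <- vapply(seq_along(mua_values), function(j) {
    v <- lut$tpsf[1, j, ]
    sum(v * lut_cell(lut, 1.0, mua_values[j])$time_ps) / sum(v)
  }, numeric(1))
  expect_true(all(diff(lut_means) < 0))
})

test_that("inconsistent white runs are rejected", {
  a <- fake_white_run(1, 10, musp = 1.0)
  b <- fake_white_run(1, 10, musp = 1.5, bin_width = 0.625, t_max = 300)
  expect_error(build_lut(list(a, b), c(0, 0.01)), "disagree")
  c2 <- fake_white_run(1, 10, musp = 0.5)
  expect_error(build_lut(list(a, c2), c(0, 0.01)), "increasing")
  expect_error(build_lut(list(), c(0, 0.01)), "non-empty")
})

test_that("lut grids validate", {
  expect_error(lut_grid(musp_values = c(1, 1)), "strictly increasing")
  expect_error(lut_grid(musp_values = c(-1, 1)), "positive")
  expect_error(lut_grid(mua_values = c(-0.01, 0)), "non-negative")
  g <- lut_grid()
  expect_length(g$musp_values, 35)
  expect_length(g$mua_values, 101)
})

test_that("a LUT survives a save/load round trip bit-exactly", {
  runs <- list(fake_white_run(c(1, 0.5), c(5, 12), musp = 1.0),
               fake_white_run(c(0.8, 0.7), c(6, 20), musp = 1.5))
  lut <- build_lut(runs, c(0, 0.02))
  path <- withr::local_tempfile(fileext = ".json")
  lut_save(lut, path)
  lut2 <- lut_load(path)
  expect_identical(lut2$tpsf, lut$tpsf)
  expect_identical(lut2$musp_values, lut$musp_values)
  expect_identical(lut2$mua_values, lut$mua_values)
  expect_equal(lut2$bin_width, lut$bin_width)

  # schema violations are named
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$bin_width <- 0.625
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(p, bad, digits = NA, auto_unbox = TRUE)
  expect_error(lut_load(bad), "bin_width")
  p2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  p2$schema <- "nope"
  jsonlite::write_json(p2, bad, digits = NA, auto_unbox = TRUE)
  expect_error(lut_load(bad), "schema")
})

test_that("lut_cell retrieves exact grid points only", {
  lut <- build_lut(list(fake_white_run(1, 10, musp = 1.0)), c(0, 0.01))
  cv <- lut_cell(lut, 1.0, 0.01)
  expect_s3_class(cv, "tpsf_curve")
  expect_equal(max(cv$intensity), 1)
  expect_error(lut_cell(lut, 1.05, 0.01), "not a grid point")
})
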