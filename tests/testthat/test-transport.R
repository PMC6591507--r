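# Elementary transport operations and the white Monte Carlo kernel.

test_that("Henyey-Greenstein sampling matches the inverse CDF and its moments", {
  # isotropic limit: cos(theta) = 2u - 1
  expect_equal(hg_sample(0, 0.5), 0)
  u <- c(0, 0.25, 0.5, 0.75, 0.999)
  expect_equal(hg_sample(0, u), 2 * u - 1)

  # g = 0.9, u = 0.5: cross-check the closed form against numerical
  # inversion of the HG cumulative distribution (independent oracle)
  g <- 0.9
  hg_cdf <- function(c) {
    (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * c) - 1 / (1 + g))
  }
  c_oracle <- uniroot(function(c) hg_cdf(c) - 0.5, c(-1, 1), tol = 1e-12)$root
  expect_equal(hg_sample(0.9, 0.5), c_oracle, tolerance = 1e-9)
  expect_equal(hg_sample(0.9, 0.5), 0.9855, tolerance = 1e-4)

  # empirical mean equals g within 3 standard errors
  set.seed(1)
  u <- runif(2e5)
  for (g in c(-0.5, 0.3, 0.9)) {
    x <- hg_sample(g, u)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se)
    expect_true(all(x >= -1 & x <= 1))
  }

  expect_error(hg_sample(1, 0.5), "strictly between")
  expect_error(hg_sample(0.5, 1), "\\[0, 1\\)")
})

test_that("free path lengths are exponential with mean 1/mus", {
  expect_equal(step_length(17, exp(-1)), 1 / 17)
  expect_equal(step_length(17, 1), 0)
  expect_error(step_length(17, 0), "\\(0, 1\\]")
  set.seed(2)
  u <- runif(1e5)
  u <- u[u > 0]
  l <- step_length(17, u)
  se <- sd(l) / sqrt(length(l))
  expect_lt(abs(mean(l) - 1 / 17), 3 * se)
})

test_that("unpolarized Fresnel reflectance matches analytic values", {
  expect_equal(fresnel_unpolarized(1.4, 1.0, 1), (0.4 / 2.4)^2)
  # symmetric under swapping the media at normal incidence
  expect_equal(fresnel_unpolarized(1.0, 1.4, 1), fresnel_unpolarized(1.4, 1.0, 1))
  # total internal reflection beyond the critical angle
  crit <- asin(1 / 1.4)
  expect_equal(fresnel_unpolarized(1.4, 1.0, cos(crit * 1.01)), 1)
  expect_equal(fresnel_unpolarized(1.4, 1.0, 0), 1)
  # in [0, 1] and continuous up to the critical angle (the slope diverges
  # like 1/sqrt(theta_c - theta), so sample finely)
  ang <- seq(0, crit - 1e-3, length.out = 4000)
  r <- fresnel_unpolarized(1.4, 1.0, cos(ang))
  expect_true(all(r >= 0 & r <= 1))
  expect_lt(max(abs(diff(r))), 0.05)
  expect_equal(r[1], (0.4 / 2.4)^2, tolerance = 1e-6)
})

test_that("time of flight converts path length at c/n", {
  expect_equal(time_of_flight(10, 1.4), 10 * 1.4 / 0.299792458)
  expect_equal(time_of_flight(10, 1.4), 46.70, tolerance = 1e-3)
  expect_equal(time_of_flight(0, 1.4), 0)
  # the implicit 300 ps cutoff corresponds to ~64.24 mm of path
  expect_equal(300 * 0.299792458 / 1.4, 64.24, tolerance = 1e-3)
})

test_that("the fiber detection condition tests spot and angle", {
  pr <- probe_geometry()
  # at the spot centre, 10 deg < asin(0.2): accepted
  expect_true(detect_check(1.25, 0, sin(10 * pi / 180), pr))
  # 15 deg exceeds the numerical aperture
  expect_false(detect_check(1.25, 0, sin(15 * pi / 180), pr))
  # 0.1 mm outside the detector radius, normal exit: rejected in spot mode
  expect_false(detect_check(1.25 + pr$detector_radius + 0.1, 0, 0, pr))
  # ...but the ring detector accepts any azimuth at the right radius
  expect_true(detect_check(0, 1.25, 0, pr, mode = "ring"))
  expect_false(detect_check(0, 1.25, 0, pr, mode = "spot"))
})

test_that("white-run weight is conserved exactly across categories", {
  w <- fat_run_crossing()
  expect_equal(w$detected_weight + w$escaped_weight + w$truncated_weight,
               w$launched_weight, tolerance = 1e-12)
  # escape estimator: the detected credit is an expectation; the physical
  # packets are all tallied escaped or truncated
  w2 <- fat_run()
  expect_equal(w2$escaped_weight + w2$truncated_weight + w2$rouletted_weight,
               w2$launched_weight, tolerance = 1e-9)
})

test_that("detected records satisfy the kinematic invariants", {
  for (w in list(fat_run(), fat_run_crossing())) {
    rec <- w$records
    expect_gt(nrow(rec), 100)
    expect_true(all(rec$weight > 0))
    expect_true(all(rec$path_length > 0))
    expect_true(all(rec$path_length <= 300 * 0.299792458 / 1.4 + 1e-9))
    expect_true(all(rec$max_depth > 0))
    expect_true(all(rec$arrival_bin >= 0 & rec$arrival_bin < 960))
    expect_true(all(rec$n_scatter >= 1))
    # arrival bin consistent with the stored path length
    expect_equal(rec$arrival_bin,
                 floor(time_of_flight(rec$path_length, 1.4) / 0.3125))
  }
})

test_that("same seed reproduces a run bit-exactly; new seed does not", {
  cfg <- sim_config(n_launched = 5e3, seed = 7)
  a <- run_white_mc(fat_medium(), fat_probe(), cfg)
  b <- run_white_mc(fat_medium(), fat_probe(), cfg)
  expect_identical(a$records, b$records)
  cfg$seed <- 8L
  c <- run_white_mc(fat_medium(), fat_probe(), cfg)
  expect_false(isTRUE(all.equal(a$detected_weight, c$detected_weight)))
})

test_that("ring and spot detection give the same TPSF shape", {
  base <- sim_config(n_launched = 4e4, seed = 11)
  spot_cfg <- sim_config(n_launched = 4e4, seed = 12, detector = "spot")
  ring <- run_white_mc(fat_medium(), fat_probe(), base)
  spot <- run_white_mc(fat_medium(), fat_probe(), spot_cfg)
  a <- coarse_fractions(rescale_to_mua(ring, 0)$intensity)
  b <- coarse_fractions(rescale_to_mua(spot, 0)$intensity)
  keep <- a > 0.01
  expect_lt(max(abs(a[keep] - b[keep]) / a[keep]), 0.2)
})

test_that("escape and crossing estimators agree in mean", {
  esc <- fat_run()
  cro <- fat_run_crossing()
  # total detected weight per launched photon
  expect_equal(esc$detected_weight / esc$n_launched,
               sum(cro$records$weight) / cro$n_launched,
               tolerance = 0.1)
  a <- coarse_fractions(rescale_to_mua(esc, 0.02)$intensity)
  b <- coarse_fractions(rescale_to_mua(cro, 0.02)$intensity)
  keep <- a > 0.02
  expect_lt(max(abs(a[keep] - b[keep]) / a[keep]), 0.25)
})

test_that("doubling the photon budget leaves the normalized TPSF within noise", {
  w1 <- run_white_mc(fat_medium(), fat_probe(),
                     sim_config(n_launched = 2e4, seed = 21))
  w2 <- run_white_mc(fat_medium(), fat_probe(),
                     sim_config(n_launched = 4e4, seed = 22))
  a <- coarse_fractions(rescale_to_mua(w1, 0)$intensity)
  b <- coarse_fractions(rescale_to_mua(w2, 0)$intensity)
  keep <- b > 0.02
  expect_lt(max(abs(a[keep] - b[keep]) / b[keep]), 0.25)
})

test_that("similarity-scaled runs reproduce direct runs", {
  pr <- fat_probe()
  cfg <- sim_config(n_launched = 5e3, seed = 31)
  direct <- run_white_mc(fat_medium(), pr, cfg)
  scaled <- run_white_mc_scaled(fat_medium()$musp, g = 0.7, n = 1.4,
                                probe = pr, config = cfg)[[1]]
  # single target at scale 1: identical records
  expect_equal(as.data.frame(direct$records), as.data.frame(scaled$records))

  # a scaled column statistically matches an independent run at that musp
  two <- run_white_mc_scaled(c(1.0, 1.5), g = 0.7, n = 1.4, probe = pr,
                             config = sim_config(n_launched = 4e4, seed = 32))
  ind <- run_white_mc(optical_properties_musp(0, 1.0, 0.7, 1.4), pr,
                      sim_config(n_launched = 4e4, seed = 33))
  a <- coarse_fractions(rescale_to_mua(two[[1]], 0.02)$intensity)
  b <- coarse_fractions(rescale_to_mua(ind, 0.02)$intensity)
  keep <- b > 0.02
  expect_lt(max(abs(a[keep] - b[keep]) / b[keep]), 0.25)
  expect_error(run_white_mc_scaled(1.7, probe = probe_geometry(immersion_depth = 0.5),
                                   config = sim_config(n_launched = 10)),
               "surface contact")
})

test_that("invalid inputs to the simulation are rejected", {
  expect_error(run_white_mc(optical_properties(0.01, 5, 0.7, 1.4), fat_probe(),
                            sim_config(n_launched = 10)),
               "mua = 0")
  expect_error(sim_config(n_launched = NULL, n_detected = NULL), "at least one")
  expect_error(sim_config(n_launched = -5), "positive")
  expect_error(sim_config(bin_width = 0.3, t_max = 1), "integer multiple")
})

test_that("white runs serialize and reload bit-exactly", {
  w <- run_white_mc(fat_medium(), fat_probe(), sim_config(n_launched = 3e3, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  white_run_save(w, path)
  w2 <- white_run_load(path)
  expect_identical(as.data.frame(w$records), as.data.frame(w2$records))
  expect_equal(w2$config_fingerprint$seed, w$config_fingerprint$seed)
  expect_equal(w2$ess, w$ess)
  expect_error(white_run_load(withr::local_tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), bad, auto_unbox = TRUE)
  expect_error(white_run_load(bad), "schema")
})
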