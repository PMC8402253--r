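test_that("spatial slope: trivial cases and both denominator conventions", {
  p <- probe_geometry(3, 5)
  expect_equal(p$rho_mean, 4)
  expect_error(probe_geometry(5, 3), "rho1 < rho2")
  s0 <- spatial_slope(intensity_pair(2, 2, "770"), p)
  expect_equal(s0$s, 0)
  # ratio e^2 over a 2 mm gap: slope exactly 1 per mm
  s1 <- spatial_slope(intensity_pair(exp(2), 1, "770"), p)
  expect_equal(s1$s, 1)
  # printed-device convention divides by the mean distance instead
  s2 <- spatial_slope(intensity_pair(exp(2), 1, "770"), p,
                      denominator = "mean")
  expect_equal(s2$s, 2 / 4)
  expect_error(intensity_pair(0, 1), "positive")
})

test_that("diffusion inversion: zero at s = 2/rho and exact closed form", {
  p <- probe_geometry(8, 12)  # rho = 10
  s <- structure(list(s = 2 / 10, wavelength = "770", probe = p,
                      denominator = "gap"), class = "slope_reading")
  expect_equal(as.numeric(mua_from_slope_diffusion(s, 1.2)), 0)
  s$s <- 0.8
  expect_equal(as.numeric(mua_from_slope_diffusion(s, 1.2)),
               (0.8 - 0.2)^2 / (3 * 1.2))
  expect_equal(as.numeric(mua_from_slope_diffusion(s, 1.2)), 0.1)
  expect_false(attr(mua_from_slope_diffusion(s, 1.2), "flagged"))
  s$s <- 0.1  # below 2/rho: ambiguous branch is flagged
  expect_true(attr(mua_from_slope_diffusion(s, 1.2), "flagged"))
  expect_error(mua_from_slope_diffusion(s, 0), "mu_s_prime")
})

test_that("closed-form diffusion intensities chain through the inversion
           to within 2% of the true absorption", {
  mu_a <- 0.0195; msp <- 1.3
  p <- probe_geometry(20, 30)
  ip <- intensity_pair(diffusion_intensity(20, mu_a, msp),
                       diffusion_intensity(30, mu_a, msp), "770")
  rec <- mua_from_slope_diffusion(spatial_slope(ip, p), msp)
  expect_lt(abs(rec - mu_a) / mu_a, 0.02)
})

test_that("explicit hemoglobin formulas match a generic 2x2 solve to 1e-12", {
  set.seed(1)
  for (i in 1:20) {
    eps <- make_extinction_table(runif(1, 0.05, 0.4), runif(1, 0.05, 0.4),
                                 runif(1, 0.05, 0.4), runif(1, 0.05, 0.4))
    mua <- runif(2, 0.001, 0.05)
    h <- hemoglobin_from_mua(mua[1], mua[2], eps)
    ref <- solve_hb_2x2(mua[1], mua[2], eps)
    expect_equal(h$o2hb, ref[1], tolerance = 1e-12)
    expect_equal(h$hhb, ref[2], tolerance = 1e-12)
    expect_identical(h$total_hb, h$o2hb + h$hhb)
  }
})

test_that("forward-inverse hemoglobin round trip is exact to 1e-12", {
  eps <- extinction_table()
  o2hb <- 0.04; hhb <- 0.02
  mua770 <- mua_of_hemoglobin(o2hb, hhb, eps, "770")
  mua830 <- mua_of_hemoglobin(o2hb, hhb, eps, "830")
  h <- hemoglobin_from_mua(mua770, mua830, eps)
  expect_equal(h$o2hb, o2hb, tolerance = 1e-12)
  expect_equal(h$hhb, hhb, tolerance = 1e-12)
  expect_equal(h$rso2, o2hb / (o2hb + hhb), tolerance = 1e-12)
  expect_false(h$low_confidence)
})

test_that("zero absorption yields zero concentrations and missing rSO2", {
  h <- hemoglobin_from_mua(0, 0, extinction_table())
  expect_equal(h$o2hb, 0)
  expect_equal(h$hhb, 0)
  expect_true(is.na(h$rso2))
  expect_true(h$low_confidence)
})

test_that("equal absorption at both wavelengths maps to ~65% saturation
           with the bundled extinction table", {
  eps <- extinction_table()
  h <- hemoglobin_from_mua(0.02, 0.02, eps)
  expect_lt(abs(h$rso2 - 0.65), 0.05)
  expect_false(h$low_confidence)
})

test_that("degenerate extinction tables are rejected", {
  expect_error(make_extinction_table(0.2, 0.2, 0.1, 0.1), "k = 0")
})

test_that("negative concentrations flag low confidence without clamping", {
  eps <- extinction_table()
  # absorption pair chosen so HHb comes out negative
  mua770 <- mua_of_hemoglobin(0.05, -0.01, eps, "770")
  mua830 <- mua_of_hemoglobin(0.05, -0.01, eps, "830")
  h <- hemoglobin_from_mua(mua770, mua830, eps)
  expect_lt(h$hhb, 0)
  expect_true(h$low_confidence)
})

test_that("slope LUT: node identity, bracketing and monotonicity", {
  p <- probe_geometry(3, 5)
  lut <- cached_run("lut_35_770", {
    build_slope_lut(mu_s = 26, g = 0.95, n = 1.4, probe = p,
                    mu_a_grid = c(0.005, 0.01, 0.02, 0.04, 0.06),
                    config = run_config(n_photons = 5e4, seed = 120),
                    method = "reweight", wavelength = "770",
                    slab_depth = 20)
  })
  expect_true(all(diff(lut$slope_values) > 0))
  # interpolation identity at the nodes
  for (i in seq_along(lut$mu_a_grid)) {
    s <- structure(list(s = lut$slope_values[i], wavelength = "770",
                        probe = p, denominator = "gap"),
                   class = "slope_reading")
    expect_equal(as.numeric(mua_from_slope_lut(s, lut)), lut$mu_a_grid[i],
                 tolerance = 1e-12)
  }
  # a slope between two nodes inverts between their absorptions
  smid <- (lut$slope_values[2] + lut$slope_values[3]) / 2
  mua <- mua_from_slope_lut(smid, lut)
  expect_gt(mua, lut$mu_a_grid[2])
  expect_lt(mua, lut$mu_a_grid[3])
  expect_false(attr(mua, "flagged"))
  # clamped and flagged outside the table
  out <- mua_from_slope_lut(max(lut$slope_values) + 1, lut)
  expect_true(attr(out, "flagged"))
  expect_equal(as.numeric(out), max(lut$mu_a_grid))
  # probe/wavelength mismatches are named errors
  s <- structure(list(s = smid, wavelength = "830", probe = p,
                      denominator = "gap"), class = "slope_reading")
  expect_error(mua_from_slope_lut(s, lut), "wavelength")
})

test_that("per-node and reweighted LUT generation agree", {
  p <- probe_geometry(3, 5)
  grid <- c(0.005, 0.015, 0.03, 0.05)
  cfg <- run_config(n_photons = 4e4, seed = 130)
  lut_rw <- build_slope_lut(10, 0.9, 1.4, p, grid, cfg,
                            method = "reweight", slab_depth = 15)
  lut_pn <- build_slope_lut(10, 0.9, 1.4, p, grid, cfg,
                            method = "per_node", slab_depth = 15)
  expect_equal(lut_rw$slope_values, lut_pn$slope_values, tolerance = 0.05)
})

test_that("slope LUT round-trips through its CSV serialization", {
  lut <- cached_run("lut_35_770", {
    build_slope_lut(mu_s = 26, g = 0.95, n = 1.4, probe = probe_geometry(3, 5),
                    mu_a_grid = c(0.005, 0.01, 0.02, 0.04, 0.06),
                    config = run_config(n_photons = 5e4, seed = 120),
                    method = "reweight", wavelength = "770",
                    slab_depth = 20)
  })
  f <- tempfile(fileext = ".csv")
  write_slope_lut(lut, f)
  lut2 <- read_slope_lut(f)
  expect_equal(lut2$mu_a_grid, lut$mu_a_grid)
  expect_equal(lut2$slope_values, lut$slope_values)
  expect_equal(lut2$probe$rho2, 5)
  expect_equal(lut2$mu_s, 26)
})

test_that("full oximeter chain: exact round trip and gain invariance", {
  eps <- extinction_table()
  p <- probe_geometry(6, 8)
  msp <- 1.2
  o2hb <- 0.03; hhb <- 0.015
  mua770 <- mua_of_hemoglobin(o2hb, hhb, eps, "770")
  mua830 <- mua_of_hemoglobin(o2hb, hhb, eps, "830")
  # construct intensities whose slope encodes those absorptions exactly
  # through the diffusion formula: s = 2/rho + sqrt(3 msp mua)
  make_pair <- function(mua, wl) {
    s <- 2 / p$rho_mean + sqrt(3 * msp * mua)
    intensity_pair(exp(s * (p$rho2 - p$rho1)), 1, wl)
  }
  h <- rso2_from_intensities(make_pair(mua770, "770"),
                             make_pair(mua830, "830"),
                             p, inversion = "diffusion", eps = eps,
                             mu_s_prime = msp)
  expect_equal(h$o2hb, o2hb, tolerance = 1e-10)
  expect_equal(h$rso2, o2hb / (o2hb + hhb), tolerance = 1e-10)
  # scaling one wavelength's intensities by any gain changes nothing
  p770 <- make_pair(mua770, "770")
  p830 <- make_pair(mua830, "830")
  p830_scaled <- intensity_pair(7.3 * p830$i_near, 7.3 * p830$i_far, "830")
  h2 <- rso2_from_intensities(p770, p830_scaled, p,
                              inversion = "diffusion", eps = eps,
                              mu_s_prime = msp)
  expect_equal(h2$rso2, h$rso2, tolerance = 1e-12)
  expect_equal(h2$total_hb, h$total_hb, tolerance = 1e-12)
})

test_that("oximeter log reader pairs wavelength rows by time stamp", {
  eps <- extinction_table()
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time = c(1, 1, 2, 2),
                       wavelength = c(770, 830, 770, 830),
                       i_near = c(10, 12, 10.5, 12.5),
                       i_far = c(2, 3, 2.1, 3.2)),
            f, row.names = FALSE)
  d <- oximeter_from_log(f, probe_geometry(6, 8),
                         inversion = "diffusion", eps = eps,
                         mu_s_prime = 1.2)
  expect_equal(nrow(d), 2L)
  expect_true(all(is.finite(d$rso2)))
})
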