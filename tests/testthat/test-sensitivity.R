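test_that("mean partial path length implements the detection-weighted mean", {
  # one detected photon, weight 0.5, 2 mm of path in one slab
  t1 <- fake_tallies(detected = c(0.5, 1),
                     path_weight = cbind(c(0.5 * 2, 0), c(0, 0)))
  expect_equal(mean_path_grid(t1, 1), c(2, 0))
  # two photons, weights 1 and 3, paths 1 and 2 mm in the same slab:
  # L = (1*1 + 2*3) / 4 = 1.75 mm
  t2 <- fake_tallies(detected = c(4, 1),
                     path_weight = cbind(c(1 * 1 + 2 * 3, 0), c(0, 0)))
  expect_equal(mean_path_grid(t2, 1), c(1.75, 0))
  # empty ring is a named error
  t3 <- fake_tallies(detected = c(1, 0), path_weight = cbind(c(1, 0), c(0, 0)))
  expect_error(mean_path_grid(t3, 2), "ring 2")
})

test_that("summed mean path equals the detection-weighted mean total path", {
  m <- make_preset_model("gastric", "770")
  cfg <- run_config(n_photons = 3000, seed = 17, voxel_size = 0.5)
  ann <- annuli_at(c(3, 5))
  rec <- propagate_photons(m, cfg, ann, n = 3000)
  t <- run_simulation(m, cfg, ann)
  for (k in 1:2) {
    det <- Filter(function(r) r$outcome == 0 && r$exit_ring == k, rec)
    w <- vapply(det, `[[`, numeric(1), "weight")
    p <- vapply(det, `[[`, numeric(1), "total_path")
    expect_equal(sum(mean_path_grid(t, k)), sum(w * p) / sum(w),
                 tolerance = 1e-9)
  }
})

test_that("sensitivity grid is far minus near and zero for equal grids", {
  g <- sensitivity_grid(c(1, 2, 3), c(1, 2, 3), pair = c(3, 5), voxel_size = 1)
  expect_equal(g$values, c(0, 0, 0))
  g2 <- sensitivity_grid(c(1, 0, 1), c(2, 1, 0), pair = c(3, 5), voxel_size = 1)
  expect_equal(g2$values, c(1, 1, -1))
  expect_error(sensitivity_grid(1:3, 1:4), "geometry")
})

test_that("depth profile sums preserve the grid total exactly", {
  a <- array(runif(4 * 3 * 5), dim = c(4, 3, 5))
  b <- array(runif(4 * 3 * 5), dim = c(4, 3, 5))
  g <- sensitivity_grid(a, b, pair = c(3, 5), voxel_size = 0.5)
  prof <- depth_profile(g)
  expect_equal(length(prof$sensitivity), 5L)
  expect_equal(sum(prof$sensitivity), sum(g$values))
  expect_equal(prof$sensitivity, apply(b - a, 3, sum))
})

test_that("profile metrics reproduce the piecewise-linear construction", {
  prof <- structure(list(depth_centers = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         sensitivity = c(0, 1, 2, 1, 0), pair = c(3, 5)),
                    class = "depth_profile")
  met <- profile_metrics(prof)
  expect_equal(met$peak_depth, 0.5)
  expect_equal(met$half_range_low, 0.3)
  expect_equal(met$half_range_high, 0.7)
  expect_equal(met$depth_10pct, 0.86)
  bad <- structure(list(depth_centers = 1:3, sensitivity = c(-1, -2, 0),
                        pair = c(3, 5)), class = "depth_profile")
  expect_error(profile_metrics(bad), "positive maximum")
})

test_that("parabolic refinement recovers an off-grid vertex", {
  xs <- seq(0.25, 4.75, by = 0.5)
  vertex <- 1.62
  ys <- 5 - (xs - vertex)^2
  prof <- structure(list(depth_centers = xs, sensitivity = ys,
                         pair = c(1, 2)), class = "depth_profile")
  expect_equal(profile_metrics(prof)$peak_depth, vertex, tolerance = 1e-9)
})

test_that("full_3d and depth_profile tallies agree for the same seed", {
  m <- make_preset_model("gastric", "770")
  ann <- annuli_at(c(3, 5))
  half <- (150 + 5.5) / 2 + 1  # max lateral reach under the path cap
  cfg3 <- run_config(n_photons = 2000, seed = 55, voxel_size = 0.5,
                     tally_mode = "full_3d", max_total_path = 150,
                     grid_xlim = c(-half, half), grid_ylim = c(-half, half),
                     grid_rings = 1:2)
  cfgd <- run_config(n_photons = 2000, seed = 55, voxel_size = 0.5,
                     max_total_path = 150)
  t3 <- run_simulation(m, cfg3, ann)
  td <- run_simulation(m, cfgd, ann)
  expect_equal(t3$detected_weight_by_ring, td$detected_weight_by_ring)
  # depth-slab tallies are computed identically in both modes
  expect_equal(t3$path_weight_by_ring, td$path_weight_by_ring)
  # the rotated, voxelized 3-D tally preserves per-depth path sums
  for (k in 1:2) {
    g <- t3$grid3d_by_ring[[match(k, t3$grid3d_rings)]]
    zsum <- apply(g, 3, sum)
    expect_equal(zsum, unname(td$path_weight_by_ring[, k]),
                 tolerance = 1e-9)
  }
})

test_that("the 0.2 mm surface layer holds both positive and negative
           sensitivity around a 3-5 mm pair", {
  t <- cached_run("surface_sign_run", {
    m <- make_preset_model("homogeneous_skin", "770")
    ann <- annuli_at(c(3, 5))
    cfg <- run_config(n_photons = 1.5e5, seed = 66, voxel_size = 0.2,
                      tally_mode = "full_3d",
                      grid_xlim = c(-3, 9), grid_ylim = c(-4, 4),
                      grid_rings = c(ring_index(ann, 3), ring_index(ann, 5)))
    run_simulation(m, cfg, ann)
  })
  ln <- mean_path_grid(t, 3, by_center = TRUE)
  lf <- mean_path_grid(t, 5, by_center = TRUE)
  g <- sensitivity_grid(ln, lf, pair = c(3, 5))
  surf <- g$values[, , 1]
  expect_gt(max(surf), 0)
  expect_lt(min(surf), 0)
  # ... but they largely cancel: the net surface sum is well below the
  # summed magnitudes, and below the profile peak (unclipped slab tallies)
  expect_lt(abs(sum(surf)), 0.5 * sum(abs(surf)))
  k3 <- ring_index(t$annuli, 3); k5 <- ring_index(t$annuli, 5)
  sens <- t$path_weight_by_ring[, k5] / t$detected_weight_by_ring[k5] -
    t$path_weight_by_ring[, k3] / t$detected_weight_by_ring[k3]
  expect_lt(sens[1], max(sens))
  expect_gt(which.max(sens), 1)  # the peak is subsurface
})

test_that("depth maps normalize every curve to a maximum of exactly 1", {
  t <- cached_run("map_small_run", {
    run_simulation(make_preset_model("gastric", "770"),
                   run_config(n_photons = 2e5, seed = 77, voxel_size = 0.5),
                   fine_annuli(10.5, width = 0.5))
  })
  map <- sweep_depth_map(tallies = t, rho2 = 5)
  expect_equal(map$rho1_values, seq(0.5, 4.5, by = 0.5))
  expect_equal(apply(map$normalized_curves, 1, max),
               rep(1, length(map$rho1_values)))
  # peak depths are consistent with the argmax of each curve
  for (i in seq_along(map$rho1_values)) {
    am <- map$depth_centers[which.max(map$normalized_curves[i, ])]
    expect_lt(abs(map$peak_depths[i] - am), 0.5)  # within one slab
  }
})

test_that("peak-depth regression recovers exact linear synthetic data", {
  pts <- expand.grid(rho1 = seq(0.5, 4.5, 0.5), rho2 = c(5, 10, 20, 30))
  pts$peak_depth <- 0.1 * pts$rho1 + 0.08 * pts$rho2 + 0.9
  fit <- fit_dp_regression(pts)
  expect_equal(fit$coef_rho1, 0.1, tolerance = 1e-12)
  expect_equal(fit$coef_rho2, 0.08, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  expect_equal(unname(predict(fit, data.frame(rho1 = 2, rho2 = 8))),
               0.1 * 2 + 0.08 * 8 + 0.9)
})

test_that("rank-deficient regression designs are rejected", {
  pts <- data.frame(rho1 = c(1, 2, 3), rho2 = c(5, 5, 5),
                    peak_depth = c(1, 2, 3))
  expect_error(fit_dp_regression(pts), "rank deficient")
  expect_error(fit_dp_regression(pts[1:2, ]), "at least 3")
})
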