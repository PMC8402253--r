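test_that("with no absorption every photon exits with weight exactly 1", {
  op <- optical_props(mu_s = 5, mu_a = 0, g = 0.8, n = 1.0)
  m <- tissue_model(tissue_layer(10, op), n_ambient = 1.0)
  cfg <- run_config(n_photons = 500, seed = 3, roulette = FALSE,
                    voxel_size = 0.5)
  ann <- annuli_at(c(2, 5))
  rec <- propagate_photons(m, cfg, ann, n = 500)
  w <- vapply(rec, `[[`, numeric(1), "weight")
  out <- vapply(rec, `[[`, numeric(1), "outcome")
  expect_true(all(out %in% c(0, 2, 3)))  # detected / transmitted / escaped
  expect_true(all(w == 1))
  t <- run_simulation(m, cfg, ann)
  expect_identical(t$absorbed_weight, 0)
})

test_that("per-slab path records sum to the total geometric path", {
  m <- make_preset_model("skin_subcutaneous", "770")
  cfg <- run_config(n_photons = 200, seed = 5, voxel_size = 0.2)
  rec <- propagate_photons(m, cfg, annuli_at(c(3, 5)), n = 200)
  for (r in rec) {
    expect_lt(abs(sum(r$path_by_slab) - r$total_path),
              1e-9 * max(1, r$total_path))
  }
})

test_that("the weight ledger closes to 1e-9 with roulette disabled", {
  for (preset in c("homogeneous_skin", "gastric")) {
    m <- make_preset_model(preset, "770")
    t <- run_simulation(m, run_config(n_photons = 1e4, seed = 21,
                                      roulette = FALSE),
                        annuli_at(c(3, 5, 6, 8)))
    led <- weight_ledger(t)
    total <- led[["detected"]] + led[["absorbed"]] + led[["transmitted"]] +
      led[["escaped"]] + led[["specular"]] + led[["lost"]]
    expect_lt(abs(total - led[["launched"]]) / led[["launched"]], 1e-9)
    expect_identical(led[["roulette_net"]], 0)
    # detected weight never exceeds what was launched
    expect_lte(sum(t$detected_weight_by_ring), t$launched)
  }
})

test_that("with roulette on, the ledger closes through the roulette net term
           and the net is zero in expectation", {
  m <- make_preset_model("homogeneous_skin", "770")
  nets <- vapply(1:12, function(s) {
    t <- run_simulation(m, run_config(n_photons = 5e3, seed = 1000 + s),
                        annuli_at(c(3, 5)))
    led <- weight_ledger(t)
    total <- sum(led[c("detected", "absorbed", "transmitted", "escaped",
                       "specular", "lost", "roulette_net")])
    expect_lt(abs(total - led[["launched"]]) / led[["launched"]], 1e-9)
    led[["roulette_net"]]
  }, numeric(1))
  se <- sd(nets) / sqrt(length(nets))
  expect_lt(abs(mean(nets)), 5 * se + 1e-12)
})

test_that("identical seed and config give identical tallies", {
  m <- make_preset_model("gastric", "770")
  cfg <- run_config(n_photons = 2e4, seed = 99)
  ann <- annuli_at(c(3, 5, 6, 8))
  t1 <- run_simulation(m, cfg, ann)
  t2 <- run_simulation(m, cfg, ann)
  expect_identical(t1$detected_weight_by_ring, t2$detected_weight_by_ring)
  expect_identical(t1$path_weight_by_ring, t2$path_weight_by_ring)
  expect_identical(weight_ledger(t1), weight_ledger(t2))
  # different seed gives different tallies
  cfg2 <- cfg; cfg2$seed <- 100
  t3 <- run_simulation(m, cfg2, ann)
  expect_false(identical(t1$detected_weight_by_ring,
                         t3$detected_weight_by_ring))
})

test_that("photon substreams extend: the first photons of a longer run
           reproduce a shorter run", {
  m <- make_preset_model("gastric", "770")
  ann <- annuli_at(c(3, 5))
  r1 <- propagate_photons(m, run_config(n_photons = 50, seed = 7), ann, n = 50)
  r2 <- propagate_photons(m, run_config(n_photons = 80, seed = 7), ann, n = 80)
  expect_identical(r1, r2[1:50])
})

test_that("diffuse reflectance decays monotonically with ring radius", {
  m <- make_preset_model("homogeneous_skin", "770")
  t <- run_simulation(m, run_config(n_photons = 3e5, seed = 31),
                      annuli_at(c(3, 5, 6, 8, 9, 14, 20, 30)))
  ri <- ring_intensities(t)
  expect_true(all(diff(ri$intensity) < 0))
  # detected weight also decays across the equal-width nominal rings
  k <- vapply(c(3, 5, 6, 8, 9, 14, 20, 30), ring_index,
              integer(1), annuli = t$annuli)
  expect_true(all(diff(ri$weight[k]) < 0))
})

test_that("total diffuse reflectance matches diffusion theory within 10%
           for a matched-boundary semi-infinite medium", {
  m <- make_preset_model("homogeneous_skin", "770", n = 1.0, n_ambient = 1.0)
  t <- run_simulation(m, run_config(n_photons = 1e5, seed = 41),
                      annuli_at(c(3, 5)))
  led <- weight_ledger(t)
  mc_refl <- (led[["detected"]] + led[["escaped"]]) / led[["launched"]]
  th_refl <- diffusion_total_reflectance(0.0195, 26 * (1 - 0.95), A = 1)
  expect_lt(abs(mc_refl - th_refl) / th_refl, 0.10)
})

test_that("full_3d mode with unreasonable grids raises the memory guard", {
  m <- make_preset_model("homogeneous_skin", "770")
  cfg <- run_config(n_photons = 10, seed = 1, voxel_size = 0.05,
                    tally_mode = "full_3d", grid_xlim = c(-200, 200),
                    grid_ylim = c(-200, 200), grid_rings = 1:2)
  expect_error(run_simulation(m, cfg, annuli_at(c(3, 5))), "depth_profile")
})

test_that("annuli constructors validate edges and locate rings", {
  expect_error(detector_annuli(c(3, 3)), "strictly increasing")
  expect_error(detector_annuli(c(-1, 2)), "non-negative")
  a <- annuli_at(c(3, 5), width = 1)
  # contiguous rings: a filler ring appears between the nominal centers
  expect_equal(a$centers, c(3, 4, 5))
  expect_equal(a$areas[c(1, 3)], pi * c(3.5^2 - 2.5^2, 5.5^2 - 4.5^2))
  expect_equal(ring_index(a, 5), 3L)
  expect_error(ring_index(a, 4.3), "no unique ring")
  f <- fine_annuli(30, width = 0.5)
  expect_equal(f$centers[1], 0.5)
  expect_equal(f$centers[length(f$centers)], 30)
})
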