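test_that("empty config yields the documented defaults", {
  cfg <- load_config()
  expect_equal(cfg$voxel_size, 0.2)
  expect_equal(cfg$roulette_threshold, 1e-4)
  expect_equal(cfg$roulette_survival, 0.1)
  expect_equal(cfg$ring_width, 1.0)
  expect_equal(cfg$tally_mode, "depth_profile")
})

test_that("validation failures name the offending key", {
  expect_error(load_config(overrides = list(voxel_size = 0)), "voxel_size")
  expect_error(load_config(overrides = list(n_photons = 0)), "n_photons")
  expect_error(load_config(overrides = list(roulette_survival = 2)),
               "roulette_survival")
  expect_error(load_config(overrides = list(pair = c(5, 3))), "pair")
  expect_error(load_config(overrides = list(nonsense_key = 1)),
               "nonsense_key")
})

test_that("configs round-trip through YAML files", {
  cfg <- load_config(overrides = list(command = "sensitivity",
                                      n_photons = 1234, seed = 9,
                                      pair = c(6, 8)))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config_to_list(cfg), f)
  cfg2 <- load_config(f)
  expect_equal(config_to_list(cfg2), config_to_list(cfg))
})

test_that("the sensitivity command writes a profile, metrics and manifest", {
  out <- tempfile()
  cfg <- load_config(overrides = list(
    command = "sensitivity", model = "gastric", n_photons = 3e4,
    seed = 5, voxel_size = 0.5, pair = c(3, 5), out_dir = out))
  res <- run_command(cfg)
  expect_true(file.exists(res$profile))
  expect_true(file.exists(res$metrics))
  expect_true(file.exists(paste0(res$profile, ".manifest.json")))
  prof <- read.csv(res$profile)
  expect_equal(names(prof), c("depth", "sensitivity"))
  met <- jsonlite::fromJSON(res$metrics)
  expect_true(met$peak_depth > 0)
  man <- jsonlite::fromJSON(paste0(res$profile, ".manifest.json"))
  expect_equal(man$config$seed, 5)
  expect_equal(unname(man$outputs$md5[1]),
               unname(tools::md5sum(res$profile)))
})

test_that("reruns with an identical config give identical output checksums", {
  mk <- function() {
    out <- tempfile()
    cfg <- load_config(overrides = list(
      command = "sensitivity", model = "gastric", n_photons = 2e4,
      seed = 11, voxel_size = 0.5, pair = c(3, 5), out_dir = out))
    tools::md5sum(run_command(cfg)$profile)
  }
  expect_equal(unname(mk()), unname(mk()))
})

test_that("the regress command recovers coefficients from fixture maps", {
  # fixture generated by the exact-linear oracle
  maps_dir <- tempfile()
  dir.create(maps_dir)
  for (r2 in c(5, 10)) {
    rho1 <- seq(0.5, r2 - 0.5, 0.5)
    write.csv(data.frame(rho1 = rho1, rho2 = r2,
                         peak_depth = 0.1 * rho1 + 0.08 * r2 + 0.9),
              file.path(maps_dir, sprintf("map%g.csv", r2)),
              row.names = FALSE)
  }
  out <- tempfile()
  cfg <- load_config(overrides = list(command = "regress",
                                      maps_dir = maps_dir, out_dir = out))
  res <- run_command(cfg)
  fit <- jsonlite::fromJSON(res$regression)
  expect_equal(fit$coef_rho1, 0.1, tolerance = 1e-10)
  expect_equal(fit$coef_rho2, 0.08, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.9, tolerance = 1e-10)
})

test_that("the table2 command emits one metrics row per standard probe", {
  out <- tempfile()
  cfg <- load_config(overrides = list(
    command = "table2", model = "gastric", n_photons = 2e5,
    seed = 13, voxel_size = 0.5, out_dir = out))
  res <- run_command(cfg)
  d <- read.csv(res$metrics)
  expect_equal(nrow(d), 4L)
  expect_equal(d$pair, c("3-5 mm", "6-8 mm", "9-14 mm", "20-30 mm"))
  expect_true(all(d$peak_depth > 0))
})

test_that("tallies persist with a verifiable manifest", {
  t <- run_simulation(make_preset_model("gastric", "770"),
                      run_config(n_photons = 1e4, seed = 2, voxel_size = 0.5),
                      annuli_at(c(3, 5)))
  f <- tempfile(fileext = ".rds")
  write_tallies(t, f)
  t2 <- read_tallies(f)
  expect_identical(t2$detected_weight_by_ring, t$detected_weight_by_ring)
  man <- jsonlite::fromJSON(paste0(f, ".manifest.json"))
  expect_equal(man$md5, unname(tools::md5sum(f)))
  expect_equal(man$n_photons, 1e4)
})
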