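# Shared Monte Carlo runs, computed lazily and reused across test files
# (test files run in one session, so an expensive run is paid for once).

.srs_test_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.srs_test_cache[[key]]))
    assign(key, force(expr), envir = .srs_test_cache)
  .srs_test_cache[[key]]
}

# Full-scale homogeneous skin-like run: serves the published depth-metric checks for
# all four detector pairs and doubles as the forward data for the
# absorption-recovery checks. Size chosen to keep the whole suite
# desk-scale; the far 20-30 mm pair is the noise-limiting consumer.
acc_homog_run <- function() {
  cached_run("acc_homog", {
    run_simulation(
      make_preset_model("homogeneous_skin", "770"),
      run_config(n_photons = 3.5e6, seed = 101, voxel_size = 0.2),
      annuli_at(c(3, 5, 6, 8, 9, 14, 20, 30), width = 1.0))
  })
}

# Full-scale layered runs with fine annuli for the peak-depth map
# sweeps and regressions (0.5 mm rings and depth slabs).
acc_skin_run <- function() {
  cached_run("acc_skin", {
    run_simulation(
      make_preset_model("skin_subcutaneous", "770"),
      run_config(n_photons = 5e6, seed = 202, voxel_size = 0.5),
      fine_annuli(30.5, width = 0.5))
  })
}

acc_gastric_run <- function() {
  cached_run("acc_gastric", {
    run_simulation(
      make_preset_model("gastric", "770"),
      run_config(n_photons = 5e6, seed = 303, voxel_size = 0.5),
      fine_annuli(30.5, width = 0.5))
  })
}

acc_maps <- function(which = c("skin", "gastric"), rho2 = c(5, 10, 20, 30)) {
  which <- match.arg(which)
  t <- if (which == "skin") acc_skin_run() else acc_gastric_run()
  lapply(rho2, function(r2) sweep_depth_map(tallies = t, rho2 = r2))
}

# A small fake tally object with known arithmetic, for unit tests of
# the sensitivity pipeline that need exact expected values.
fake_tallies <- function(detected, path_weight, voxel_size = 1,
                         centers = seq_along(detected)) {
  ann <- annuli_at(centers, width = 0.5)
  structure(list(
    detected_weight_by_ring = detected,
    path_weight_by_ring = path_weight,
    launched = sum(detected),
    n_slabs = nrow(path_weight),
    depth_centers = (seq_len(nrow(path_weight)) - 0.5) * voxel_size,
    annuli = ann,
    config = run_config(n_photons = 1, voxel_size = voxel_size),
    wavelength = "770", model_label = "fake"
  ), class = "srs_tallies")
}
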