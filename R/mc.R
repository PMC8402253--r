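#' Detector annuli on the tissue surface
#'
#' Detectors are concentric annular rings around the source axis; ring k
#' is the half-open radial interval `[edge_k, edge_{k+1})`. A pencil
#' beam on laterally homogeneous layers is cylindrically symmetric, so a
#' ring at radius rho collects every photon a point detector at
#' distance rho would see, at far better statistics.
#'
#' @param ring_edges Strictly increasing non-negative radii, mm.
#' @return An object of class `detector_annuli` with element
#'   `ring_edges` and derived `centers` and `areas` (mm^2).
#' @seealso [annuli_at()], [fine_annuli()]
#' @export
detector_annuli <- function(ring_edges) {
  stopifnot(is.numeric(ring_edges), length(ring_edges) >= 2L)
  if (any(ring_edges < 0) || any(diff(ring_edges) <= 0))
    stop("ring_edges must be non-negative and strictly increasing",
         call. = FALSE)
  e <- as.numeric(ring_edges)
  structure(list(
    ring_edges = e,
    centers = (e[-length(e)] + e[-1]) / 2,
    areas = pi * (e[-1]^2 - e[-length(e)]^2)
  ), class = "detector_annuli")
}

#' Annuli centered on nominal source-detector distances
#'
#' @param centers Nominal distances, mm (strictly increasing; the rings
#'   must not overlap).
#' @param width Ring width, mm (default 1.0).
#' @export
annuli_at <- function(centers, width = 1.0) {
  stopifnot(is.numeric(centers), all(centers > 0), width > 0)
  centers <- sort(unique(as.numeric(centers)))
  e <- sort(unique(round(c(centers - width / 2, centers + width / 2), 9)))
  a <- detector_annuli(e)
  a$nominal_centers <- centers
  a
}

#' Fine contiguous annuli for map sweeps
#'
#' Contiguous rings of constant width spanning `[width/2, r_max + width/2)`
#' so that ring centers fall on `width, 2*width, ...` -- every
#' source-detector pair on that grid can be read from one simulation.
#'
#' @param r_max Largest ring center, mm.
#' @param width Ring width, mm (default 0.5).
#' @export
fine_annuli <- function(r_max, width = 0.5) {
  stopifnot(r_max >= width)
  detector_annuli(seq(width / 2, r_max + width / 2 + 1e-9, by = width))
}

#' Locate the ring whose center matches a nominal distance
#'
#' @param annuli A [detector_annuli()].
#' @param rho Nominal distance, mm.
#' @param tol Center-matching tolerance, mm.
#' @return Ring index (1-based).
#' @export
ring_index <- function(annuli, rho, tol = 1e-6) {
  stopifnot(inherits(annuli, "detector_annuli"))
  k <- which(abs(annuli$centers - rho) < tol)
  if (length(k) != 1L)
    stop(sprintf("no unique ring centered at %g mm", rho), call. = FALSE)
  k
}

#' Monte Carlo run configuration
#'
#' @param n_photons Number of launched photons (>= 1).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical tallies. Each photon draws from its own
#'   counter-derived substream, so changing `n_photons` extends rather
#'   than reshuffles the photon sequence.
#' @param voxel_size Tally voxel/slab edge, mm (default 0.2; use 0.5 for
#'   map sweeps to keep memory and noise manageable).
#' @param tally_mode `"depth_profile"` (per-depth-slab path sums;
#'   default) or `"full_3d"` (adds per-voxel 3-D tallies for the rings
#'   in `grid_rings`, with detected paths rotated about the z axis so
#'   the exit point lies on +x before binning).
#' @param roulette_threshold Weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival Survival probability of the roulette
#'   (default 0.1); surviving photons have their weight divided by it.
#' @param roulette Logical; disable to make the weight ledger close
#'   exactly (conservation tests).
#' @param max_total_path Cap on the total geometric path, mm; photons
#'   exceeding it are terminated and their weight tallied as lost.
#' @param grid_xlim,grid_ylim Lateral extents of the 3-D tally grid, mm
#'   (full_3d mode only).
#' @param grid_rings Ring indices that receive a 3-D grid (full_3d
#'   mode); default both rings of interest must be given explicitly.
#' @param path_hist Logical; also tally per-ring histograms of total
#'   detected path length (used by the absorption-reweighting lookup
#'   table builder).
#' @param path_hist_bin,path_hist_max Histogram bin width and upper
#'   bound, mm.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_photons, seed = 1L, voxel_size = 0.2,
                       tally_mode = c("depth_profile", "full_3d"),
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       roulette = TRUE, max_total_path = 1e4,
                       grid_xlim = NULL, grid_ylim = NULL,
                       grid_rings = integer(),
                       path_hist = FALSE, path_hist_bin = 2,
                       path_hist_max = NULL) {
  tally_mode <- match.arg(tally_mode)
  stopifnot(is.numeric(n_photons), length(n_photons) == 1L)
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0", call. = FALSE)
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)", call. = FALSE)
  if (roulette_threshold < 0)
    stop("roulette_threshold must be >= 0", call. = FALSE)
  if (max_total_path <= 0) stop("max_total_path must be > 0", call. = FALSE)
  if (is.null(path_hist_max)) path_hist_max <- max_total_path
  structure(list(
    n_photons = as.numeric(n_photons), seed = as.numeric(seed),
    voxel_size = voxel_size, tally_mode = tally_mode,
    roulette_threshold = roulette_threshold,
    roulette_survival = roulette_survival, roulette = roulette,
    max_total_path = max_total_path,
    grid_xlim = grid_xlim, grid_ylim = grid_ylim,
    grid_rings = as.integer(grid_rings),
    path_hist = isTRUE(path_hist), path_hist_bin = path_hist_bin,
    path_hist_max = path_hist_max
  ), class = "run_config")
}

#' Sample the Henyey-Greenstein phase function
#'
#' Deflection cosines from the Henyey-Greenstein distribution with mean
#' cosine `g` (isotropic when `g = 0`) and azimuths uniform on
#' `[0, 2*pi)`.
#'
#' @param n Number of samples.
#' @param g Anisotropy factor in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with numeric vectors `cos_theta` and `azimuth`.
#' @export
sample_scatter_hg <- function(n, g, seed = 1L) {
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g >= 1)
    stop("g must lie in [0, 1)", call. = FALSE)
  stopifnot(n >= 1)
  cpp_sample_hg(as.numeric(n), g, as.numeric(seed))
}

.simulate_raw <- function(model, config, annuli, wavelength, n_records = 0L) {
  stopifnot(inherits(model, "tissue_model"), inherits(config, "run_config"),
            inherits(annuli, "detector_annuli"))
  lm_ <- layer_matrix(model, wavelength)
  full3d <- config$tally_mode == "full_3d"
  if (full3d) {
    if (is.null(config$grid_xlim) || is.null(config$grid_ylim))
      stop("full_3d mode needs grid_xlim and grid_ylim", call. = FALSE)
    if (length(config$grid_rings) < 1L)
      stop("full_3d mode needs grid_rings (ring indices to grid)",
           call. = FALSE)
    nx <- ceiling(diff(config$grid_xlim) / config$voxel_size)
    ny <- ceiling(diff(config$grid_ylim) / config$voxel_size)
    nz <- ceiling(model_thickness(model) / config$voxel_size)
    bytes <- nx * ny * nz * length(config$grid_rings) * 8
    if (bytes > 4e9)
      stop(sprintf(paste0(
        "full_3d tally would need ~%.1f GiB; use depth_profile mode, ",
        "coarser voxels or a smaller grid"), bytes / 2^30), call. = FALSE)
    gspec <- c(config$grid_xlim[1], config$grid_xlim[2],
               config$grid_ylim[1], config$grid_ylim[2])
    grings <- config$grid_rings - 1L
  } else {
    gspec <- numeric(4)
    grings <- integer()
  }
  cpp_run_simulation(
    lm_, model$n_ambient, model$n_ambient,
    config$n_photons, config$seed, config$voxel_size,
    annuli$ring_edges, if (full3d) 1L else 0L,
    config$roulette, config$roulette_threshold, config$roulette_survival,
    config$max_total_path, gspec, grings, as.integer(n_records),
    config$path_hist, config$path_hist_bin, config$path_hist_max)
}

#' Run a Monte Carlo simulation and collect detector tallies
#'
#' Launches `config$n_photons` weighted photons as a pencil beam at the
#' origin pointing into the tissue and tallies, for every detector
#' ring, the detected weight (the sum of intensities `I_i`) and the
#' per-depth-slab path-length weight (the sum of `L_i * I_i`), the raw
#' ingredients of the detection-weighted mean partial path length.
#'
#' @param model A [tissue_model()].
#' @param config A [run_config()].
#' @param annuli A [detector_annuli()].
#' @param wavelength Wavelength label; defaults to the model's
#'   `default_wavelength` attribute, else `"770"`.
#' @return An object of class `srs_tallies`: detected and path-weight
#'   tallies per ring, the weight ledger (launched, absorbed,
#'   transmitted, escaped-outside-rings, specular, lost, roulette net),
#'   depth-slab centers, and echoes of the inputs.
#' @export
run_simulation <- function(model, config, annuli, wavelength = NULL) {
  if (is.null(wavelength)) {
    wavelength <- attr(model, "default_wavelength")
    if (is.null(wavelength)) wavelength <- "770"
  }
  raw <- .simulate_raw(model, config, annuli, wavelength)
  nz <- raw$n_slabs
  structure(c(raw, list(
    depth_centers = (seq_len(nz) - 0.5) * config$voxel_size,
    annuli = annuli, config = config, wavelength = normalize_wavelength(wavelength),
    model_label = model$label, model_config = model_to_config(model)
  )), class = "srs_tallies")
}

#' @export
print.srs_tallies <- function(x, ...) {
  cat(sprintf("SRS Monte Carlo tallies: %s photons, %d rings, %d depth slabs of %.2g mm\n",
              format(x$launched, big.mark = ","),
              length(x$detected_weight_by_ring), x$n_slabs,
              x$config$voxel_size))
  led <- weight_ledger(x)
  cat(sprintf("  ledger: detected %.4f, absorbed %.4f, transmitted %.4f, escaped %.4f, specular %.4f (of launched weight)\n",
              led["detected"] / led["launched"],
              led["absorbed"] / led["launched"],
              led["transmitted"] / led["launched"],
              led["escaped"] / led["launched"],
              led["specular"] / led["launched"]))
  invisible(x)
}

#' Weight conservation ledger of a run
#'
#' With roulette disabled the components sum to the launched weight to
#' floating-point accuracy; with roulette on, the roulette net term
#' restores exact closure (it is zero in expectation).
#'
#' @param tallies An `srs_tallies` object.
#' @return Named numeric vector.
#' @export
weight_ledger <- function(tallies) {
  stopifnot(inherits(tallies, "srs_tallies"))
  c(launched = tallies$launched,
    detected = tallies$detected_total,
    absorbed = tallies$absorbed_weight,
    transmitted = tallies$transmitted_weight,
    escaped = tallies$escaped_outside_weight,
    specular = tallies$specular_weight,
    lost = tallies$lost_weight,
    roulette_net = tallies$roulette_net_weight)
}

#' Detected intensity per ring
#'
#' Detected weight divided by the exact annulus area: an estimate of the
#' diffuse reflectance (per mm^2 per launched photon when
#' `normalize = TRUE`).
#'
#' @param tallies An `srs_tallies` object.
#' @param normalize Divide by the launched photon count (default TRUE).
#' @return Data frame with columns `center`, `area`, `weight`,
#'   `intensity`.
#' @export
ring_intensities <- function(tallies, normalize = TRUE) {
  stopifnot(inherits(tallies, "srs_tallies"))
  w <- tallies$detected_weight_by_ring
  a <- tallies$annuli$areas
  data.frame(center = tallies$annuli$centers, area = a, weight = w,
             intensity = w / a / if (normalize) tallies$launched else 1)
}

#' Trace individual photons and return their outcome records
#'
#' Debug/oracle-level access to the transport kernel: propagates `n`
#' photons and returns, for each, the outcome (detected, roulette-killed,
#' transmitted, escaped outside the rings, or path-capped), exit radius
#' and weight, total geometric path, and the per-depth-slab path record.
#'
#' @inheritParams run_simulation
#' @param n Number of photons to trace (kept small; every record holds a
#'   full slab vector).
#' @return List of per-photon records.
#' @export
propagate_photons <- function(model, config, annuli, n = 10L,
                              wavelength = NULL) {
  if (is.null(wavelength)) {
    wavelength <- attr(model, "default_wavelength")
    if (is.null(wavelength)) wavelength <- "770"
  }
  config$n_photons <- as.numeric(n)
  raw <- .simulate_raw(model, config, annuli, wavelength, n_records = n)
  raw$photon_records
}

#' Persist tallies to disk with a JSON manifest
#'
#' The tally arrays are written as an RDS container and a JSON manifest
#' (seed, configuration, model, photon count, ledger totals, checksum)
#' is placed alongside, so any output can be regenerated and verified.
#'
#' @param tallies An `srs_tallies` object.
#' @param path Output path for the RDS file; the manifest gets the same
#'   path with extension `.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_tallies <- function(tallies, path) {
  stopifnot(inherits(tallies, "srs_tallies"))
  saveRDS(tallies, path)
  manifest <- list(
    tool = paste0("srsdepth ", as.character(utils::packageVersion("srsdepth"))),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = tallies$config$seed,
    n_photons = tallies$config$n_photons,
    voxel_size = tallies$config$voxel_size,
    tally_mode = tallies$config$tally_mode,
    wavelength = tallies$wavelength,
    model = tallies$model_config,
    ledger = as.list(weight_ledger(tallies)),
    file = basename(path),
    md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load tallies written by [write_tallies()]
#' @param path Path to the RDS file.
#' @export
read_tallies <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "srs_tallies"))
  x
}
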