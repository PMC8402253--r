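# SRS oximetry chain: spatial slope of the detected intensity,
# absorption inversion (closed-form diffusion approximation or Monte
# Carlo lookup table), two-wavelength hemoglobin concentrations and
# regional oxygen saturation rSO2.

#' Two-detector probe geometry
#'
#' @param rho1 Near source-detector distance, mm.
#' @param rho2 Far source-detector distance, mm (> rho1).
#' @param label Optional probe label.
#' @return Object of class `probe_geometry` with `rho_mean =
#'   (rho1 + rho2) / 2`.
#' @export
probe_geometry <- function(rho1, rho2, label = sprintf("%g-%g mm", rho1, rho2)) {
  stopifnot(is.numeric(rho1), is.numeric(rho2))
  if (!(rho1 > 0 && rho2 > rho1))
    stop("need 0 < rho1 < rho2", call. = FALSE)
  structure(list(rho1 = rho1, rho2 = rho2,
                 rho_mean = (rho1 + rho2) / 2, label = label),
            class = "probe_geometry")
}

#' The four probe geometries of the oximeter family
#'
#' Detector offsets 3/5, 6/8, 9/14 and 20/30 mm.
#' @return Named list of [probe_geometry()] objects.
#' @export
standard_probes <- function() {
  list(`3-5`  = probe_geometry(3, 5),
       `6-8`  = probe_geometry(6, 8),
       `9-14` = probe_geometry(9, 14),
       `20-30` = probe_geometry(20, 30))
}

#' A pair of detected intensities at one wavelength
#'
#' @param i_near,i_far Detected intensities at rho1 and rho2, arbitrary
#'   but common linear units (> 0).
#' @param wavelength Wavelength label.
#' @export
intensity_pair <- function(i_near, i_far, wavelength = "770") {
  if (!is.numeric(i_near) || !is.numeric(i_far) || i_near <= 0 || i_far <= 0)
    stop("intensities must be positive", call. = FALSE)
  structure(list(i_near = i_near, i_far = i_far,
                 wavelength = normalize_wavelength(wavelength)),
            class = "intensity_pair")
}

#' Spatial slope of the detected intensity
#'
#' Two-point estimate of the decay slope of `ln I` with distance:
#' `s = ln(i_near / i_far) / (rho2 - rho1)` (per mm). The
#' `denominator = "mean"` mode divides by the mean distance
#' `(rho1 + rho2) / 2` instead, reproducing the printed device formula
#' verbatim; the default `"gap"` form is the dimensionally consistent
#' finite-difference estimate of `-d ln I / d rho` that the diffusion
#' inversion presumes.
#'
#' @param pair An [intensity_pair()].
#' @param probe A [probe_geometry()].
#' @param denominator `"gap"` (default, rho2 - rho1) or `"mean"` (rho).
#' @return Object of class `slope_reading` with fields `s` (per mm),
#'   `wavelength`, `probe`, `denominator`.
#' @export
spatial_slope <- function(pair, probe, denominator = c("gap", "mean")) {
  stopifnot(inherits(pair, "intensity_pair"), inherits(probe, "probe_geometry"))
  denominator <- match.arg(denominator)
  den <- if (denominator == "gap") probe$rho2 - probe$rho1 else probe$rho_mean
  structure(list(s = log(pair$i_near / pair$i_far) / den,
                 wavelength = pair$wavelength, probe = probe,
                 denominator = denominator),
            class = "slope_reading")
}

#' Absorption coefficient from the spatial slope (diffusion formula)
#'
#' Closed-form inversion valid in the diffusion regime:
#' `mu_a = (s - 2 / rho)^2 / (3 mu_s')` with `rho` the mean
#' source-detector distance of the probe. The result carries a
#' `flagged` attribute when `s <= 2 / rho`, where the square is blind to
#' the sign and the inversion is ambiguous.
#'
#' @param s A `slope_reading` (or a plain slope in per mm together with
#'   `rho`).
#' @param mu_s_prime Assumed reduced scattering coefficient, per mm (> 0).
#' @param rho Mean source-detector distance, mm (only when `s` is
#'   numeric).
#' @return Absorption coefficient, per mm, with attribute `flagged`.
#' @export
mua_from_slope_diffusion <- function(s, mu_s_prime, rho = NULL) {
  if (!is.numeric(mu_s_prime) || mu_s_prime <= 0)
    stop("mu_s_prime must be > 0", call. = FALSE)
  if (inherits(s, "slope_reading")) {
    rho <- s$probe$rho_mean
    s <- s$s
  }
  stopifnot(is.numeric(s), is.numeric(rho), rho > 0)
  mua <- (s - 2 / rho)^2 / (3 * mu_s_prime)
  attr(mua, "flagged") <- s <= 2 / rho
  mua
}

#' Build a slope-to-absorption lookup table by Monte Carlo
#'
#' At short source-detector distances the diffusion formula is biased,
#' so the device inverts the slope through a Monte Carlo reference
#' table instead: for each absorption value on a grid, simulate the
#' homogeneous medium with the probe's two detector rings and record
#' the spatial slope; inversion then interpolates the monotone
#' slope-to-absorption map.
#'
#' Two generation methods are available. `"per_node"` runs one
#' independent simulation per grid value on a shared seed schedule
#' (seed + node index). `"reweight"` runs a single zero-absorption
#' simulation that tallies per-ring histograms of total path length L
#' and evaluates every node as `I(mu_a) = sum_i w_i exp(-mu_a L_i)`:
#' trajectories are then sampled from the scattering interaction
#' density, and the exponential factor is the exact absorption weight
#' along the stored paths, so the estimate is unbiased for any mu_a on
#' the grid at a fraction of the cost.
#'
#' @param mu_s,g,n Scattering coefficient (per mm), anisotropy and
#'   refractive index of the assumed homogeneous medium.
#' @param probe A [probe_geometry()].
#' @param mu_a_grid Strictly increasing absorption grid, per mm (>= 4
#'   values).
#' @param config A [run_config()]; `n_photons` applies per node
#'   (`"per_node"`) or once (`"reweight"`).
#' @param method `"reweight"` (default) or `"per_node"`.
#' @param wavelength Wavelength label stored on the table.
#' @param ring_width Detector ring width, mm.
#' @param n_ambient Ambient refractive index.
#' @param slab_depth Thickness of the simulated homogeneous slab, mm.
#' @param denominator Slope convention, see [spatial_slope()].
#' @return Object of class `slope_lut`.
#' @export
build_slope_lut <- function(mu_s, g, n = 1.4, probe, mu_a_grid, config,
                            method = c("reweight", "per_node"),
                            wavelength = "770", ring_width = 1.0,
                            n_ambient = 1.0, slab_depth = 40,
                            denominator = c("gap", "mean")) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  stopifnot(inherits(probe, "probe_geometry"), inherits(config, "run_config"))
  if (length(mu_a_grid) < 4L || any(diff(mu_a_grid) <= 0) || any(mu_a_grid < 0))
    stop("mu_a_grid must be non-negative, strictly increasing, >= 4 points",
         call. = FALSE)
  ann <- annuli_at(c(probe$rho1, probe$rho2), width = ring_width)
  k1 <- ring_index(ann, probe$rho1)
  k2 <- ring_index(ann, probe$rho2)
  wl <- normalize_wavelength(wavelength)
  den <- if (denominator == "gap") probe$rho2 - probe$rho1 else probe$rho_mean

  slope_of <- function(w1, w2) {
    i1 <- w1 / ann$areas[k1]
    i2 <- w2 / ann$areas[k2]
    log(i1 / i2) / den
  }

  if (method == "per_node") {
    slopes <- vapply(seq_along(mu_a_grid), function(i) {
      mdl <- tissue_model(
        tissue_layer(slab_depth,
                     optical_props(mu_s, mu_a_grid[i], g, n)),
        label = "lut_node", n_ambient = n_ambient)
      cfg <- config
      cfg$seed <- config$seed + i - 1
      t <- run_simulation(mdl, cfg, ann, wavelength = wl)
      w <- t$detected_weight_by_ring
      if (any(w[c(k1, k2)] <= 0))
        stop("a detector ring received no photons; increase n_photons",
             call. = FALSE)
      slope_of(w[k1], w[k2])
    }, numeric(1))
  } else {
    mdl <- tissue_model(
      tissue_layer(slab_depth, optical_props(mu_s, 0, g, n)),
      label = "lut_base", n_ambient = n_ambient)
    cfg <- config
    cfg$path_hist <- TRUE
    if (is.null(cfg$path_hist_bin) || cfg$path_hist_bin > 2)
      cfg$path_hist_bin <- 1
    cfg$path_hist_max <- min(cfg$max_total_path, 4000)
    t <- run_simulation(mdl, cfg, ann, wavelength = wl)
    h <- t$path_hist_by_ring
    if (any(colSums(h)[c(k1, k2)] <= 0))
      stop("a detector ring received no photons; increase n_photons",
           call. = FALSE)
    mids <- (seq_len(nrow(h)) - 0.5) * t$config$path_hist_bin
    slopes <- vapply(mu_a_grid, function(mua) {
      att <- exp(-mua * mids)
      slope_of(sum(h[, k1] * att), sum(h[, k2] * att))
    }, numeric(1))
  }

  if (any(diff(slopes) <= 0))
    stop(paste0("slope sequence is not strictly increasing with mu_a ",
                "(Monte Carlo noise exceeds the grid spacing); ",
                "increase n_photons or widen the grid"), call. = FALSE)
  structure(list(probe = probe, wavelength = wl,
                 mu_a_grid = as.numeric(mu_a_grid),
                 slope_values = slopes,
                 mu_s = mu_s, g = g, n = n,
                 method = method, denominator = denominator,
                 n_photons = config$n_photons, seed = config$seed,
                 ring_width = ring_width),
            class = "slope_lut")
}

#' @export
print.slope_lut <- function(x, ...) {
  cat(sprintf("slope LUT, probe %s at %s nm (%s): mu_a %g..%g /mm -> slope %.4f..%.4f /mm\n",
              x$probe$label, x$wavelength, x$method,
              min(x$mu_a_grid), max(x$mu_a_grid),
              min(x$slope_values), max(x$slope_values)))
  invisible(x)
}

#' Write / read a slope lookup table as CSV with header metadata
#'
#' @param lut A `slope_lut`.
#' @param path CSV path; metadata travels in `#`-prefixed header lines.
#' @export
write_slope_lut <- function(lut, path) {
  stopifnot(inherits(lut, "slope_lut"))
  meta <- sprintf(
    "# slope_lut probe=%g,%g wavelength=%s mu_s=%g g=%g n=%g method=%s denominator=%s n_photons=%g seed=%g ring_width=%g",
    lut$probe$rho1, lut$probe$rho2, lut$wavelength, lut$mu_s, lut$g, lut$n,
    lut$method, lut$denominator, lut$n_photons, lut$seed, lut$ring_width)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(data.frame(mu_a = lut$mu_a_grid, slope = lut$slope_values),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_slope_lut
#' @export
read_slope_lut <- function(path) {
  meta <- readLines(path, n = 1L)
  if (!startsWith(meta, "# slope_lut"))
    stop("not a slope LUT file", call. = FALSE)
  kv <- regmatches(meta, gregexpr("[a-z_]+=[^ ]+", meta))[[1]]
  vals <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  d <- utils::read.csv(path, comment.char = "#")
  pr <- as.numeric(strsplit(vals[["probe"]], ",")[[1]])
  structure(list(probe = probe_geometry(pr[1], pr[2]),
                 wavelength = vals[["wavelength"]],
                 mu_a_grid = d$mu_a, slope_values = d$slope,
                 mu_s = as.numeric(vals[["mu_s"]]),
                 g = as.numeric(vals[["g"]]), n = as.numeric(vals[["n"]]),
                 method = vals[["method"]],
                 denominator = vals[["denominator"]],
                 n_photons = as.numeric(vals[["n_photons"]]),
                 seed = as.numeric(vals[["seed"]]),
                 ring_width = as.numeric(vals[["ring_width"]])),
            class = "slope_lut")
}

#' Absorption coefficient from the spatial slope (lookup table)
#'
#' Monotone piecewise-linear interpolation of the inverse
#' slope-to-absorption map. Slopes outside the tabulated range are
#' clamped to the nearest node and flagged.
#'
#' @param s A `slope_reading` (its probe and wavelength must match the
#'   table) or a plain numeric slope, per mm.
#' @param lut A `slope_lut`.
#' @return Absorption coefficient, per mm, with attribute `flagged`
#'   (TRUE when the slope fell outside the table).
#' @export
mua_from_slope_lut <- function(s, lut) {
  stopifnot(inherits(lut, "slope_lut"))
  if (inherits(s, "slope_reading")) {
    if (abs(s$probe$rho1 - lut$probe$rho1) > 1e-9 ||
        abs(s$probe$rho2 - lut$probe$rho2) > 1e-9)
      stop("slope reading and LUT use different probes", call. = FALSE)
    if (!identical(s$wavelength, lut$wavelength))
      stop("slope reading and LUT use different wavelengths", call. = FALSE)
    if (!identical(s$denominator, lut$denominator))
      stop("slope reading and LUT use different slope conventions",
           call. = FALSE)
    s <- s$s
  }
  out_of_range <- s < min(lut$slope_values) | s > max(lut$slope_values)
  mua <- stats::approx(lut$slope_values, lut$mu_a_grid, xout = s,
                       rule = 2)$y
  attr(mua, "flagged") <- out_of_range
  mua
}

#' Extinction coefficient table for O2Hb and HHb at 770 / 830 nm
#'
#' Loads the bundled table (widely used compiled molar extinction
#' spectra of human hemoglobin, converted to natural-log absorption per
#' mm per mmol/L) or a user-supplied CSV with columns `wavelength_nm`,
#' `eps_o2hb`, `eps_hhb` containing rows for 770 and 830 nm in the same
#' units. The determinant `k = eps770_O2Hb * eps830_HHb - eps830_O2Hb *
#' eps770_HHb` is precomputed.
#'
#' @param path Optional CSV path; default uses the bundled table.
#' @return Object of class `extinction_table` with fields
#'   `eps_o2hb_770`, `eps_o2hb_830`, `eps_hhb_770`, `eps_hhb_830`, `k`.
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hb_extinction.csv", package = "srsdepth")
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_o2hb", "eps_hhb")
  stopifnot(all(need %in% names(d)))
  row770 <- d[d$wavelength_nm == 770, ]
  row830 <- d[d$wavelength_nm == 830, ]
  if (nrow(row770) != 1L || nrow(row830) != 1L)
    stop("table must contain exactly one row each for 770 and 830 nm",
         call. = FALSE)
  make_extinction_table(row770$eps_o2hb, row830$eps_o2hb,
                        row770$eps_hhb, row830$eps_hhb)
}

#' Assemble an extinction table from four coefficients
#'
#' @param eps_o2hb_770,eps_o2hb_830,eps_hhb_770,eps_hhb_830 Extinction
#'   coefficients, per mm per (mmol/L), natural-log convention.
#' @export
make_extinction_table <- function(eps_o2hb_770, eps_o2hb_830,
                                  eps_hhb_770, eps_hhb_830) {
  k <- eps_o2hb_770 * eps_hhb_830 - eps_o2hb_830 * eps_hhb_770
  if (!is.finite(k) || k == 0)
    stop("degenerate extinction table: k = 0 (wavelengths not independent)",
         call. = FALSE)
  structure(list(eps_o2hb_770 = eps_o2hb_770, eps_o2hb_830 = eps_o2hb_830,
                 eps_hhb_770 = eps_hhb_770, eps_hhb_830 = eps_hhb_830,
                 k = k),
            class = "extinction_table")
}

#' Total tissue absorption of a hemoglobin mixture
#'
#' Forward model `mu_a = eps_O2Hb * [O2Hb] + eps_HHb * [HHb]` at one
#' wavelength (useful for constructing test media and phantoms).
#'
#' @param o2hb,hhb Concentrations, mmol/L.
#' @param eps An `extinction_table`.
#' @param wavelength `"770"` or `"830"`.
#' @return Absorption coefficient, per mm.
#' @export
mua_of_hemoglobin <- function(o2hb, hhb, eps, wavelength) {
  wl <- normalize_wavelength(wavelength)
  if (wl == "770") eps$eps_o2hb_770 * o2hb + eps$eps_hhb_770 * hhb
  else eps$eps_o2hb_830 * o2hb + eps$eps_hhb_830 * hhb
}

#' Hemoglobin concentrations and rSO2 from a two-wavelength absorption pair
#'
#' Solves the 2 x 2 extinction system in the standard explicit form:
#' `[O2Hb] = (eps830_HHb mu_a770 - eps770_HHb mu_a830) / k`,
#' `[HHb] = -(eps830_O2Hb mu_a770 - eps770_O2Hb mu_a830) / k`, then
#' `rSO2 = [O2Hb] / ([O2Hb] + [HHb])`.
#'
#' @param mu_a_770,mu_a_830 Absorption coefficients, per mm. Either may
#'   carry a `flagged` attribute from the inversion step, which
#'   propagates into `low_confidence`.
#' @param eps An `extinction_table`.
#' @param total_hb_floor Total hemoglobin (mmol/L) below which the
#'   result is marked low confidence: with very little blood the slope
#'   spectrum reflects scattering rather than hemoglobin and the ratio
#'   is unreliable.
#' @return Object of class `hemoglobin_result` with fields `o2hb`,
#'   `hhb`, `total_hb` (mmol/L), `rso2` (fraction, `NA` when
#'   `total_hb <= 0`), `low_confidence`.
#' @export
hemoglobin_from_mua <- function(mu_a_770, mu_a_830, eps,
                                total_hb_floor = 1e-3) {
  stopifnot(inherits(eps, "extinction_table"))
  flagged_in <- isTRUE(attr(mu_a_770, "flagged")) ||
    isTRUE(attr(mu_a_830, "flagged"))
  mu_a_770 <- as.numeric(mu_a_770)
  mu_a_830 <- as.numeric(mu_a_830)
  o2hb <- (eps$eps_hhb_830 * mu_a_770 - eps$eps_hhb_770 * mu_a_830) / eps$k
  hhb <- -(eps$eps_o2hb_830 * mu_a_770 - eps$eps_o2hb_770 * mu_a_830) / eps$k
  total <- o2hb + hhb
  rso2 <- if (total > 0) o2hb / total else NA_real_
  low_conf <- flagged_in || o2hb < 0 || hhb < 0 ||
    !is.finite(total) || total < total_hb_floor
  structure(list(o2hb = unname(o2hb), hhb = unname(hhb),
                 total_hb = unname(total), rso2 = unname(rso2),
                 low_confidence = low_conf),
            class = "hemoglobin_result")
}

#' @export
print.hemoglobin_result <- function(x, ...) {
  cat(sprintf("O2Hb %.4g, HHb %.4g, totalHb %.4g mmol/L; rSO2 %s%s\n",
              x$o2hb, x$hhb, x$total_hb,
              if (is.na(x$rso2)) "NA" else sprintf("%.1f%%", 100 * x$rso2),
              if (x$low_confidence) "  [low confidence]" else ""))
  invisible(x)
}

#' Regional oxygen saturation from raw two-wavelength intensities
#'
#' Composes the full oximeter computation: spatial slope per wavelength,
#' absorption inversion (diffusion formula or lookup table), hemoglobin
#' concentrations, rSO2. Scaling both intensities of one wavelength by
#' any positive constant (detector gain) leaves the result unchanged,
#' since only the intensity ratio enters the slope.
#'
#' @param reading_770,reading_830 [intensity_pair()] objects at the two
#'   wavelengths.
#' @param probe A [probe_geometry()]; both readings must share it.
#' @param inversion `"diffusion"` or `"lut"`.
#' @param eps An [extinction_table()].
#' @param mu_s_prime Assumed reduced scattering, per mm: a single value
#'   shared by both wavelengths or a named vector
#'   `c("770" = ..., "830" = ...)` (diffusion inversion only).
#' @param lut_770,lut_830 `slope_lut` objects (lut inversion only).
#' @param denominator Slope convention, see [spatial_slope()].
#' @param total_hb_floor See [hemoglobin_from_mua()].
#' @return A `hemoglobin_result`.
#' @export
rso2_from_intensities <- function(reading_770, reading_830, probe,
                                  inversion = c("diffusion", "lut"),
                                  eps = extinction_table(),
                                  mu_s_prime = NULL,
                                  lut_770 = NULL, lut_830 = NULL,
                                  denominator = c("gap", "mean"),
                                  total_hb_floor = 1e-3) {
  inversion <- match.arg(inversion)
  denominator <- match.arg(denominator)
  stopifnot(inherits(reading_770, "intensity_pair"),
            inherits(reading_830, "intensity_pair"))
  if (!identical(reading_770$wavelength, "770") ||
      !identical(reading_830$wavelength, "830"))
    stop("readings must be labelled 770 and 830 nm", call. = FALSE)
  s770 <- spatial_slope(reading_770, probe, denominator)
  s830 <- spatial_slope(reading_830, probe, denominator)
  if (inversion == "diffusion") {
    if (is.null(mu_s_prime))
      stop("diffusion inversion needs mu_s_prime", call. = FALSE)
    msp <- if (length(mu_s_prime) == 1L && is.null(names(mu_s_prime)))
      c(`770` = unname(mu_s_prime), `830` = unname(mu_s_prime))
    else mu_s_prime
    mua770 <- mua_from_slope_diffusion(s770, msp[["770"]])
    mua830 <- mua_from_slope_diffusion(s830, msp[["830"]])
  } else {
    if (is.null(lut_770) || is.null(lut_830))
      stop("lut inversion needs lut_770 and lut_830", call. = FALSE)
    mua770 <- mua_from_slope_lut(s770, lut_770)
    mua830 <- mua_from_slope_lut(s830, lut_830)
  }
  hemoglobin_from_mua(mua770, mua830, eps, total_hb_floor = total_hb_floor)
}

#' Read an intensity log and run the oximeter over it
#'
#' The log is columnar text (CSV) with columns `time`, `wavelength`,
#' `i_near`, `i_far`; consecutive 770/830 rows sharing a time stamp are
#' paired.
#'
#' @param path Input CSV path.
#' @param probe A [probe_geometry()].
#' @param ... Passed to [rso2_from_intensities()].
#' @return Data frame with one row per time stamp: `time`, `o2hb`,
#'   `hhb`, `total_hb`, `rso2`, `low_confidence`.
#' @export
oximeter_from_log <- function(path, probe, ...) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time", "wavelength", "i_near", "i_far") %in% names(d)))
  times <- unique(d$time)
  rows <- lapply(times, function(tm) {
    sub <- d[d$time == tm, ]
    r770 <- sub[sub$wavelength %in% c(770, "770", "770 nm"), ]
    r830 <- sub[sub$wavelength %in% c(830, "830", "830 nm"), ]
    if (nrow(r770) != 1L || nrow(r830) != 1L)
      stop(sprintf("time %s lacks a 770/830 pair", tm), call. = FALSE)
    h <- rso2_from_intensities(
      intensity_pair(r770$i_near, r770$i_far, "770"),
      intensity_pair(r830$i_near, r830$i_far, "830"),
      probe, ...)
    data.frame(time = tm, o2hb = h$o2hb, hhb = h$hhb,
               total_hb = h$total_hb, rso2 = h$rso2,
               low_confidence = h$low_confidence)
  })
  do.call(rbind, rows)
}
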