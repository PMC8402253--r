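# In-silico analogue of the blood-layer phantom experiment: a thin,
# fully oxygenated blood-bearing layer at a variable depth inside a
# fat-like (Intralipid + agar) scattering medium, measured with the SRS
# probes through the full oximetry chain.

#' Parametric description of the blood-layer phantom
#'
#' The bench phantom this emulates is agar with 1.2% Intralipid as the
#' scattering background and, in one thin layer, 1% oxygenated whole
#' blood. The background optics are nominal Intralipid-like values
#' (reduced scattering ~1.2 per mm with the g = 0.7 convention, small
#' background absorption), not values reported for the bench phantom.
#'
#' @param blood_thickness Thickness of the blood-bearing layer, mm.
#' @param blood_volume_fraction Volume fraction of whole blood in that
#'   layer (default 0.01, i.e. 1%).
#' @param blood_total_hb Total hemoglobin of whole blood, mmol/L
#'   (default 2.3, a standard physiological value ~150 g/L).
#' @param blood_saturation Oxygen saturation of the blood (default 1.0,
#'   fully oxygenated).
#' @param background Named list of [optical_props()] per wavelength for
#'   the blood-free medium (default Intralipid-like: mu_s 4 per mm,
#'   g 0.7, mu_a 0.002 per mm, both wavelengths).
#' @param bottom_thickness Blood-free medium below the blood layer, mm.
#' @param n Refractive index for default background layers (agar is
#'   mostly water; 1.33).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(blood_thickness = 1.0, blood_volume_fraction = 0.01,
                         blood_total_hb = 2.3, blood_saturation = 1.0,
                         background = NULL, bottom_thickness = 30,
                         n = 1.33) {
  stopifnot(blood_thickness > 0, bottom_thickness > 0,
            blood_volume_fraction >= 0, blood_volume_fraction <= 1,
            blood_saturation >= 0, blood_saturation <= 1,
            blood_total_hb >= 0)
  if (is.null(background)) {
    bg <- optical_props(mu_s = 4, mu_a = 0.002, g = 0.7, n = n)
    background <- list(`770` = bg, `830` = bg)
  }
  stopifnot(is.list(background),
            all(c("770", "830") %in% names(background)))
  structure(list(blood_thickness = blood_thickness,
                 blood_volume_fraction = blood_volume_fraction,
                 blood_total_hb = blood_total_hb,
                 blood_saturation = blood_saturation,
                 background = background,
                 bottom_thickness = bottom_thickness),
            class = "phantom_spec")
}

#' Optical properties of the blood-bearing layer
#'
#' Absorption is the background value plus the hemoglobin contribution
#' `blood_volume_fraction * blood_total_hb * (saturation * eps_O2Hb +
#' (1 - saturation) * eps_HHb)` at the wavelength; scattering is
#' inherited from the background (1% blood adds negligible scattering
#' next to 1.2% Intralipid).
#'
#' @param spec A [phantom_spec()].
#' @param eps An [extinction_table()].
#' @param wavelength `"770"` or `"830"`.
#' @return An [optical_props()] object.
#' @export
blood_layer_props <- function(spec, eps, wavelength) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(eps, "extinction_table"))
  wl <- normalize_wavelength(wavelength)
  bg <- spec$background[[wl]]
  c_hb <- spec$blood_volume_fraction * spec$blood_total_hb
  mua_blood <- mua_of_hemoglobin(spec$blood_saturation * c_hb,
                                 (1 - spec$blood_saturation) * c_hb,
                                 eps, wl)
  optical_props(mu_s = bg$mu_s, mu_a = bg$mu_a + mua_blood,
                g = bg$g, n = bg$n)
}

#' Build the layered tissue model of the phantom at one blood depth
#'
#' Background slab of thickness `blood_depth`, blood-bearing layer,
#' background bottom slab. A zero blood depth puts the blood layer at
#' the surface (the degenerate top slab is omitted).
#'
#' @param spec A [phantom_spec()].
#' @param blood_depth Depth of the top of the blood layer, mm (>= 0).
#' @param wavelength `"770"` or `"830"`.
#' @param eps An [extinction_table()].
#' @return A [tissue_model()].
#' @export
build_phantom_model <- function(spec, blood_depth, wavelength,
                                eps = extinction_table()) {
  stopifnot(inherits(spec, "phantom_spec"), blood_depth >= 0)
  wl <- normalize_wavelength(wavelength)
  bg <- spec$background[[wl]]
  blood <- blood_layer_props(spec, eps, wl)
  layers <- list()
  if (blood_depth > 0)
    layers <- c(layers, list(tissue_layer(blood_depth, bg, name = "background")))
  layers <- c(layers, list(tissue_layer(spec$blood_thickness, blood,
                                        name = "blood layer")))
  layers <- c(layers, list(tissue_layer(spec$bottom_thickness, bg,
                                        name = "background")))
  m <- tissue_model(layers,
                    label = sprintf("phantom_blood_at_%.2fmm", blood_depth),
                    n_ambient = 1.0)
  attr(m, "default_wavelength") <- wl
  m
}

#' Sweep the blood-layer depth and measure rSO2 with each probe
#'
#' For each blood depth, simulates the phantom at both wavelengths
#' (same seed schedule and a single annulus set covering all probes, so
#' every probe is read from the same pair of runs), then runs the SRS
#' oximetry chain per probe and records the apparent rSO2. Depths are
#' reported at the blood-layer middle (a layer spanning 1-2 mm is
#' plotted at 1.5 mm).
#'
#' @param spec A [phantom_spec()].
#' @param probes List of [probe_geometry()] (default [standard_probes()]).
#' @param depths Depths of the blood-layer top, mm.
#' @param config A [run_config()]; the same seed drives every depth and
#'   both wavelengths (common random numbers), so the depth response and
#'   the 770/830 differential reflect the optics rather than trajectory
#'   resampling noise.
#' @param eps An [extinction_table()].
#' @param inversion `"diffusion"` (default; the assumed `mu_s_prime` is
#'   the background's reduced scattering per wavelength) or `"lut"`.
#' @param luts For `"lut"`: named list per probe label of
#'   `list(lut_770 =, lut_830 =)`.
#' @param ring_width Detector ring width, mm.
#' @param total_hb_floor See [hemoglobin_from_mua()].
#' @return Data frame: `probe`, `blood_depth` (top), `depth`
#'   (mid-layer), `rso2`, `total_hb`, `low_confidence`.
#' @export
phantom_depth_sweep <- function(spec, probes = standard_probes(), depths,
                                config, eps = extinction_table(),
                                inversion = c("diffusion", "lut"),
                                luts = NULL, ring_width = 1.0,
                                total_hb_floor = 1e-3) {
  inversion <- match.arg(inversion)
  stopifnot(inherits(spec, "phantom_spec"), inherits(config, "run_config"))
  centers <- sort(unique(unlist(lapply(probes, function(p) c(p$rho1, p$rho2)))))
  ann <- annuli_at(centers, width = ring_width)
  msp <- vapply(c("770", "830"), function(wl) mu_s_prime(spec$background[[wl]]),
                numeric(1))
  rows <- list()
  for (i in seq_along(depths)) {
    d <- depths[i]
    ints <- lapply(c("770", "830"), function(wl) {
      cfg <- config
      mdl <- build_phantom_model(spec, d, wl, eps)
      t <- run_simulation(mdl, cfg, ann, wavelength = wl)
      ring_intensities(t)
    })
    names(ints) <- c("770", "830")
    for (pn in names(probes)) {
      p <- probes[[pn]]
      k1 <- which(abs(ann$centers - p$rho1) < 1e-9)
      k2 <- which(abs(ann$centers - p$rho2) < 1e-9)
      pair_of <- function(wl) {
        ii <- ints[[wl]]
        if (ii$weight[k1] <= 0 || ii$weight[k2] <= 0)
          stop(sprintf("probe %s received no photons at depth %g", pn, d),
               call. = FALSE)
        intensity_pair(ii$intensity[k1], ii$intensity[k2], wl)
      }
      h <- if (inversion == "diffusion") {
        rso2_from_intensities(pair_of("770"), pair_of("830"), p,
                              inversion = "diffusion", eps = eps,
                              mu_s_prime = msp,
                              total_hb_floor = total_hb_floor)
      } else {
        rso2_from_intensities(pair_of("770"), pair_of("830"), p,
                              inversion = "lut", eps = eps,
                              lut_770 = luts[[pn]]$lut_770,
                              lut_830 = luts[[pn]]$lut_830,
                              total_hb_floor = total_hb_floor)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe = pn, blood_depth = d,
        depth = d + spec$blood_thickness / 2,
        rso2 = h$rso2, total_hb = h$total_hb,
        low_confidence = h$low_confidence)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
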