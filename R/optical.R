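#' Optical properties of a turbid medium at one wavelength
#'
#' Bundles the scattering coefficient, absorption coefficient, scattering
#' anisotropy and refractive index of one tissue layer at one wavelength.
#' The reduced scattering coefficient `mu_s * (1 - g)` is derived, not
#' stored; retrieve it with [mu_s_prime()].
#'
#' @param mu_s Scattering coefficient, mm^-1 (>= 0).
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param g Scattering anisotropy factor (mean cosine of the deflection
#'   angle), in `[0, 1)`.
#' @param n Refractive index (>= 1). Defaults to 1.4, the usual tissue
#'   convention in layered Monte Carlo codes.
#' @return An object of class `optical_props`.
#' @examples
#' op <- optical_props(mu_s = 26, mu_a = 0.02, g = 0.95)
#' mu_s_prime(op)  # 1.3 mm^-1
#' @export
optical_props <- function(mu_s, mu_a, g, n = 1.4) {
  stopifnot(is.numeric(mu_s), length(mu_s) == 1L,
            is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(g), length(g) == 1L,
            is.numeric(n), length(n) == 1L)
  if (mu_s < 0) stop("mu_s must be >= 0", call. = FALSE)
  if (mu_a < 0) stop("mu_a must be >= 0", call. = FALSE)
  if (g < 0 || g >= 1) stop("g must lie in [0, 1)", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  structure(list(mu_s = mu_s, mu_a = mu_a, g = g, n = n),
            class = "optical_props")
}

#' Reduced scattering coefficient
#'
#' @param x An [optical_props()] object.
#' @return `mu_s * (1 - g)`, mm^-1.
#' @export
mu_s_prime <- function(x) {
  stopifnot(inherits(x, "optical_props"))
  x$mu_s * (1 - x$g)
}

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf(
    "optical properties: mu_s = %g /mm, mu_a = %g /mm, g = %g, n = %g (mu_s' = %g /mm)\n",
    x$mu_s, x$mu_a, x$g, x$n, mu_s_prime(x)))
  invisible(x)
}

#' A tissue layer with per-wavelength optical properties
#'
#' @param thickness Layer thickness, mm (> 0).
#' @param props Named list mapping wavelength labels (`"770"`, `"830"`)
#'   to [optical_props()] objects. A single `optical_props` object is
#'   accepted and used for both wavelengths.
#' @param name Optional layer name.
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(thickness, props, name = "") {
  stopifnot(is.numeric(thickness), length(thickness) == 1L)
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  if (inherits(props, "optical_props")) {
    props <- list(`770` = props, `830` = props)
  }
  stopifnot(is.list(props), length(props) >= 1L)
  if (is.null(names(props)) || any(!nzchar(names(props))))
    stop("props must be a named list keyed by wavelength label", call. = FALSE)
  for (p in props) {
    if (!inherits(p, "optical_props"))
      stop("each props entry must be an optical_props object", call. = FALSE)
  }
  structure(list(thickness = thickness, props = props, name = name),
            class = "tissue_layer")
}

#' Layered slab tissue model
#'
#' Layers are ordered top (illuminated surface) first. Photons crossing
#' the bottom of the last layer escape and are tallied as transmitted;
#' they are never re-entered.
#'
#' @param layers List of [tissue_layer()] objects, top first.
#' @param label Free-text model label.
#' @param n_ambient Refractive index of the ambient medium above the
#'   surface (and below the bottom boundary). Default 1.0 (air).
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(layers, label = "", n_ambient = 1.0) {
  if (inherits(layers, "tissue_layer")) layers <- list(layers)
  stopifnot(is.list(layers), length(layers) >= 1L)
  for (l in layers) {
    if (!inherits(l, "tissue_layer"))
      stop("layers must be tissue_layer objects", call. = FALSE)
  }
  depths <- cumsum(vapply(layers, `[[`, numeric(1), "thickness"))
  if (any(diff(c(0, depths)) <= 0))
    stop("cumulative interface depths must be strictly increasing", call. = FALSE)
  structure(list(layers = layers, label = label,
                 n_ambient = n_ambient, bottom_boundary = "escape"),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("tissue model%s: %d layer(s), total thickness %.2f mm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$layers), model_thickness(x)))
  wl <- names(x$layers[[1]]$props)[1]
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    p <- l$props[[wl]]
    cat(sprintf("  %d. %-10s %6.2f mm  (at %s nm: mu_s %g, mu_a %g, g %g, n %g)\n",
                i, if (nzchar(l$name)) l$name else "layer",
                l$thickness, wl, p$mu_s, p$mu_a, p$g, p$n))
  }
  invisible(x)
}

#' Total model thickness in mm
#' @param model A [tissue_model()].
#' @export
model_thickness <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  sum(vapply(model$layers, `[[`, numeric(1), "thickness"))
}

#' Extract the per-layer property matrix at one wavelength
#'
#' Internal bridge to the transport kernel: one row per layer with
#' columns thickness, mu_s, mu_a, g, n.
#'
#' @param model A [tissue_model()].
#' @param wavelength Wavelength label, `"770"` or `"830"` (numerics accepted).
#' @return Numeric matrix, one row per layer.
#' @export
layer_matrix <- function(model, wavelength = "770") {
  stopifnot(inherits(model, "tissue_model"))
  wl <- normalize_wavelength(wavelength)
  m <- matrix(NA_real_, nrow = length(model$layers), ncol = 5,
              dimnames = list(NULL, c("thickness", "mu_s", "mu_a", "g", "n")))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    p <- l$props[[wl]]
    if (is.null(p))
      stop(sprintf("layer %d has no optical properties at %s nm", i, wl),
           call. = FALSE)
    m[i, ] <- c(l$thickness, p$mu_s, p$mu_a, p$g, p$n)
  }
  m
}

normalize_wavelength <- function(wavelength) {
  wl <- as.character(wavelength)
  wl <- sub("\\s*nm$", "", wl)
  if (!wl %in% c("770", "830"))
    stop(sprintf("unknown wavelength '%s' (expected 770 or 830)", wavelength),
         call. = FALSE)
  wl
}

#' Serialize a tissue model to a plain-list configuration
#'
#' The list mirrors the YAML/JSON on-disk schema: per layer
#' `thickness_mm` plus per wavelength `mu_s_per_mm`, `mu_a_per_mm`, `g`,
#' `n`. Round trips through [model_from_config()] exactly.
#'
#' @param model A [tissue_model()].
#' @return A plain list.
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  list(
    label = model$label,
    n_ambient = model$n_ambient,
    layers = lapply(model$layers, function(l) {
      list(name = l$name,
           thickness_mm = l$thickness,
           wavelengths = lapply(l$props, function(p) {
             list(mu_s_per_mm = p$mu_s, mu_a_per_mm = p$mu_a,
                  g = p$g, n = p$n)
           }))
    }))
}

#' Build a tissue model from a configuration list or file
#'
#' @param config A list with the schema of [model_to_config()], or a
#'   path to a YAML/JSON file holding one.
#' @return A [tissue_model()].
#' @export
model_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  stopifnot(is.list(config), !is.null(config$layers))
  layers <- lapply(config$layers, function(l) {
    props <- lapply(l$wavelengths, function(p) {
      optical_props(mu_s = p$mu_s_per_mm, mu_a = p$mu_a_per_mm,
                    g = p$g, n = if (is.null(p$n)) 1.4 else p$n)
    })
    tissue_layer(thickness = l$thickness_mm, props = props,
                 name = if (is.null(l$name)) "" else l$name)
  })
  tissue_model(layers,
               label = if (is.null(config$label)) "" else config$label,
               n_ambient = if (is.null(config$n_ambient)) 1.0 else config$n_ambient)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
}
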