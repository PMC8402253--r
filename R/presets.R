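# Optical-property presets for the simulation models.
#
# Scattering coefficients carry one value per wavelength (770 nm first,
# 830 nm second); absorption and anisotropy are shared across the two
# wavelengths (absorption of the hemoglobin-perfused tissues is nearly
# equal at 770 and 830 nm when tissue saturation is ~65%, so a single
# value is used). Units: mm^-1 for coefficients, mm for thickness.
.tissue_table <- list(
  skin    = list(thickness = 1.5,  mu_s = c(`770` = 26, `830` = 23),
                 mu_a = 0.020, g = 0.95),
  fat     = list(thickness = 2.5,  mu_s = c(`770` = 24, `830` = 22),
                 mu_a = 0.003, g = 0.95),
  muscle  = list(thickness = 20.0, mu_s = c(`770` = 14, `830` = 13),
                 mu_a = 0.025, g = 0.95),
  gastric = list(thickness = 7.0,  mu_s = c(`770` = 15, `830` = 14),
                 mu_a = 0.030, g = 0.92)
)

# Mean absorption over the four tissue types: used by the homogeneous
# skin-like model.
.mean_mu_a <- mean(vapply(.tissue_table, `[[`, numeric(1), "mu_a"))

# The homogeneous model is nominally semi-infinite; 40 mm with bottom
# escape is deep enough that escape through the bottom is negligible for
# source-detector distances up to 30 mm.
.homogeneous_depth_mm <- 40

.preset_layer <- function(tissue, wavelengths, n, thickness = NULL) {
  row <- .tissue_table[[tissue]]
  props <- lapply(stats::setNames(wavelengths, wavelengths), function(wl) {
    optical_props(mu_s = unname(row$mu_s[[wl]]), mu_a = row$mu_a,
                  g = row$g, n = n)
  })
  tissue_layer(thickness = if (is.null(thickness)) row$thickness else thickness,
               props = props, name = tissue)
}

#' Construct a preset layered tissue model
#'
#' Three presets are available:
#' \describe{
#'   \item{`homogeneous_skin`}{A single thick (40 mm) layer with skin
#'     scattering and the mean absorption coefficient of the four tissue
#'     types (0.0195 mm^-1) -- the semi-infinite homogeneous skin-like
#'     medium used for the detector-pair sensitivity analysis.}
#'   \item{`skin_subcutaneous`}{Skin (1.5 mm) / fat (2.5 mm) / muscle
#'     (20 mm) stack.}
#'   \item{`gastric`}{A single 7.0 mm gastric-wall slab with bottom
#'     escape (light leaving the far surface of the thin wall is lost).}
#' }
#'
#' Both wavelength entries (770 and 830 nm) are populated in every
#' preset so two-wavelength operations can use the same model object;
#' `wavelength` selects which one downstream single-wavelength
#' simulations default to (stored as attribute `default_wavelength`).
#'
#' @param name Preset name.
#' @param wavelength Default wavelength label, `"770"` (default) or `"830"`.
#' @param n Tissue refractive index (all layers), default 1.4.
#' @param n_ambient Ambient refractive index, default 1.0. Set both to 1
#'   for matched-boundary (diffusion-limit) studies.
#' @return A [tissue_model()] with attribute `default_wavelength`.
#' @examples
#' make_preset_model("skin_subcutaneous", "770")
#' @export
make_preset_model <- function(name = c("homogeneous_skin", "skin_subcutaneous",
                                       "gastric"),
                              wavelength = "770", n = 1.4, n_ambient = 1.0) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("homogeneous_skin", "skin_subcutaneous", "gastric"))
    stop(sprintf("unknown preset '%s'", paste(name, collapse = ",")),
         call. = FALSE)
  wl <- normalize_wavelength(wavelength)
  wls <- c("770", "830")
  model <- switch(
    name,
    homogeneous_skin = {
      skin <- .tissue_table$skin
      props <- lapply(stats::setNames(wls, wls), function(w) {
        optical_props(mu_s = unname(skin$mu_s[[w]]), mu_a = .mean_mu_a,
                      g = skin$g, n = n)
      })
      tissue_model(tissue_layer(.homogeneous_depth_mm, props,
                                name = "skin-like"),
                   label = "homogeneous_skin", n_ambient = n_ambient)
    },
    skin_subcutaneous = tissue_model(
      list(.preset_layer("skin", wls, n),
           .preset_layer("fat", wls, n),
           .preset_layer("muscle", wls, n)),
      label = "skin_subcutaneous", n_ambient = n_ambient),
    gastric = tissue_model(.preset_layer("gastric", wls, n),
                           label = "gastric", n_ambient = n_ambient)
  )
  attr(model, "default_wavelength") <- wl
  model
}
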