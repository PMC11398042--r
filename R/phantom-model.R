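#' Default effective attenuation coefficients
#'
#' Effective linear attenuation coefficients (mm^-1) per material over a grid
#' of tube voltages. A single effective coefficient per (material, kV) stands
#' in for the polyenergetic beam: coefficients decrease with kV, and the
#' high-Z materials (aluminum, bone) fall off much faster than soft tissue,
#' which is what shifts the wedge scale down relative to tissue as kV rises.
#'
#' The aluminum values are calibrated so that, with the default wedge and HU
#' map, the thinnest step's mean value at each preset sits at the midpoint of
#' the reference ranges shipped with the package (see [reference_ranges()]).
#'
#' @return A named list, one entry per material, each a list with numeric
#'   vectors `kv` and `mu`.
#' @export
default_mu_table <- function() {
  kv <- c(40, 50, 60, 70, 80, 90)
  al <- c(0.3350, 0.3000, 0.2687, 0.1787, 0.1488, 0.1250)
  list(
    air         = list(kv = kv, mu = rep(0, length(kv))),
    aluminum    = list(kv = kv, mu = al),
    bone        = list(kv = kv, mu = 0.55 * al),
    soft_tissue = list(kv = kv, mu = c(0.0212, 0.0208, 0.0202, 0.0196, 0.0190, 0.0186))
  )
}

#' Generative model for synthetic radiographs
#'
#' Holds everything the renderer needs: the per-material attenuation table,
#' the affine map from optical depth (sum of mu * thickness over materials
#' along a ray) to Hounsfield-like values, and the noise model.
#'
#' The HU map is anchored at air: zero path length maps to `hu_air`
#' (-1000 HU) and values increase linearly with optical depth at
#' `hu_gain` HU per unit. Raising mAs widens the spread between step values
#' through a dispersion gain `1 + mas_dispersion * log10(mas / mas_ref)`
#' while the quantum-noise standard deviation shrinks as `1/sqrt(mas)`, so
#' high-mAs calibrations show scattered, non-adjacent step ranges.
#'
#' @param mu_table Material attenuation table, as [default_mu_table()].
#' @param hu_gain HU per unit optical depth (dimensionless mu*t).
#' @param hu_air HU value of zero path length (air), -1000 by convention.
#' @param mas_dispersion Dispersion gain coefficient per decade of mAs.
#' @param mas_ref Reference mAs at which the dispersion gain is 1.
#' @param noise_sd Gaussian noise standard deviation in HU at `mas_ref` and
#'   `noise_kv_ref`.
#' @param noise_kv_ref Reference kV for the contrast scaling of the noise: a
#'   low tube voltage produces a high-contrast image, so both the wedge
#'   scale and the HU fluctuations contract with rising kV; the noise sd is
#'   multiplied by the aluminum attenuation ratio mu(kV)/mu(noise_kv_ref).
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(mu_table = default_mu_table(), hu_gain = 1000,
                          hu_air = -1000, mas_dispersion = 0.35,
                          mas_ref = 1.2, noise_sd = 55, noise_kv_ref = 50) {
  stopifnot(is.list(mu_table), hu_gain > 0, noise_sd >= 0, mas_ref > 0)
  for (m in names(mu_table)) {
    tab <- mu_table[[m]]
    if (is.unsorted(tab$kv, strictly = TRUE)) {
      stop("mu table kV grid must be strictly increasing for material ", m)
    }
    if (any(tab$mu < 0)) stop("attenuation coefficients must be >= 0 for ", m)
  }
  structure(
    list(mu_table = mu_table, hu_gain = hu_gain, hu_air = hu_air,
         mas_dispersion = mas_dispersion, mas_ref = mas_ref,
         noise_sd = noise_sd, noise_kv_ref = noise_kv_ref),
    class = "phantom_model"
  )
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("<phantom_model>\n")
  cat("  materials:", paste(names(x$mu_table), collapse = ", "), "\n")
  cat(sprintf("  hu_map: HU = %g * optical_depth %+g (air anchor)\n",
              x$hu_gain, x$hu_air))
  cat(sprintf("  noise: sd %g HU at %g mAs (~ 1/sqrt(mAs))\n",
              x$noise_sd, x$mas_ref))
  invisible(x)
}

#' Effective linear attenuation coefficient of a material
#'
#' Looks up (and linearly interpolates inside the tabulated kV grid) the
#' effective attenuation coefficient of a material at a given tube voltage.
#' Air is non-attenuating by definition and returns 0 at any kV. No
#' extrapolation is performed outside the tabulated grid.
#'
#' @param material Material name present in `model$mu_table`.
#' @param kv Tube voltage in kilovolt.
#' @param model A [phantom_model()].
#' @return Attenuation coefficient in mm^-1.
#' @export
effective_mu <- function(material, kv, model = phantom_model()) {
  if (!material %in% names(model$mu_table)) {
    stop("unknown material: '", material, "'")
  }
  if (material == "air") return(0)
  tab <- model$mu_table[[material]]
  if (kv < min(tab$kv) || kv > max(tab$kv)) {
    stop("kV ", kv, " outside the tabulated range [", min(tab$kv), ", ",
         max(tab$kv), "] for material '", material, "'")
  }
  stats::approx(tab$kv, tab$mu, xout = kv)$y
}

#' Map optical depth to Hounsfield-like values
#'
#' Applies the model's affine HU map, including the mAs dispersion gain.
#'
#' @param a Optical depth (sum over materials of mu * thickness), any shape.
#' @param exposure An [exposure_setting()].
#' @param model A [phantom_model()].
#' @return HU-like values with the shape of `a`.
#' @export
hu_from_attenuation <- function(a, exposure, model = phantom_model()) {
  gain <- model$hu_gain *
    (1 + model$mas_dispersion * log10(exposure$mas / model$mas_ref))
  gain * a + model$hu_air
}

#' Noise standard deviation at a given exposure
#'
#' Quantum-noise convention in mAs (sd proportional to 1/sqrt(mAs)) combined
#' with contrast scaling in kV: the HU fluctuations contract together with
#' the gray scale as the beam gets more penetrating, so the sd is multiplied
#' by mu_aluminum(kV) / mu_aluminum(noise_kv_ref).
#'
#' @inheritParams hu_from_attenuation
#' @return Standard deviation in HU.
#' @export
noise_sd_at <- function(exposure, model = phantom_model()) {
  contrast <- effective_mu("aluminum", exposure$kv, model) /
    effective_mu("aluminum", model$noise_kv_ref, model)
  model$noise_sd * sqrt(model$mas_ref / exposure$mas) * contrast
}
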