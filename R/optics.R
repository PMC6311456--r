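#' Optical properties of the propagation medium
#'
#' Bundle of the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index used by the photon-transport engine.
#'
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param mu_s Scattering coefficient (mm^-1), >= 0.
#' @param g Scattering anisotropy (mean cosine of the Henyey-Greenstein
#'   deflection), in `[-1, 1]`.
#' @param n_medium Refractive index of the medium, >= 1. Brain tissue is
#'   taken as 1.36.
#' @return An object of class `optical_properties`.
#' @seealso [optical_preset()] for the built-in tissue and water presets.
#' @export
optical_properties <- function(mu_a, mu_s, g, n_medium = 1.36) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s))
  if (mu_a < 0 || mu_s < 0)
    stop("mu_a and mu_s must be non-negative", call. = FALSE)
  if (abs(g) > 1) stop("anisotropy g must lie in [-1, 1]", call. = FALSE)
  if (n_medium < 1) stop("n_medium must be >= 1", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n_medium = n_medium),
            class = "optical_properties")
}

#' Built-in optical presets
#'
#' Brain-tissue properties at the GCaMP excitation (490 nm) and emission
#' (512 nm) wavelengths, with hemoglobin-dominated absorption (3% blood
#' volume, 15 g/dL hemoglobin, 70% oxygenation) and standard cortical
#' scattering (mu_s = 20 mm^-1, g = 0.9), plus a ballistic "water" medium
#' with negligible absorption and scattering.
#'
#' @param name One of `"tissue490"`, `"tissue512"`, `"water"`.
#' @return An `optical_properties` object carrying a `wavelength` attribute.
#' @export
optical_preset <- function(name = c("tissue490", "tissue512", "water")) {
  name <- match.arg(name)
  props <- switch(name,
    tissue490 = optical_properties(mu_a = 0.337, mu_s = 20, g = 0.9),
    tissue512 = optical_properties(mu_a = 0.343, mu_s = 20, g = 0.9),
    water     = optical_properties(mu_a = 0, mu_s = 0, g = 0, n_medium = 1.33)
  )
  attr(props, "wavelength") <- switch(name, tissue490 = 490, tissue512 = 512,
                                      water = NA_real_)
  attr(props, "preset") <- name
  props
}

# Approximate molar extinction coefficients of hemoglobin (cm^-1 M^-1),
# compiled literature values; adequate for order-of-magnitude absorption
# estimates in the blue-green band.
hemoglobin_extinction <- data.frame(
  wavelength = seq(460, 560, by = 10),
  eps_hbo2 = c(44496, 33209, 26629, 23388, 20932, 20035, 24202, 39956,
               53236, 43016, 32613),
  eps_hb   = c(30584, 22510, 17570, 16156, 20862, 25774, 29372, 30832,
               38536, 48940, 53412)
)

#' Hemoglobin-dominated tissue absorption coefficient
#'
#' Estimates the absorption coefficient of perfused tissue from its blood
#' content: `mu_a = BVF * ln(10) * [SO2*eps_HbO2 + (1-SO2)*eps_Hb] * C / M`,
#' with C the hemoglobin mass concentration and M = 64500 g/mol its molar
#' mass. This is a helper for exploring wavelengths; the built-in presets
#' use fixed printed coefficients.
#'
#' @param blood_volume_fraction Fraction of tissue volume that is blood,
#'   in `[0, 1]` (default 0.03).
#' @param hb_concentration Hemoglobin concentration in blood, g/dL
#'   (default 15).
#' @param oxygen_saturation Fraction of hemoglobin that is oxygenated,
#'   in `[0, 1]` (default 0.7).
#' @param wavelength Wavelength in nm; must lie within the embedded
#'   extinction table (460-560 nm); linearly interpolated.
#' @param extinction_table Data frame with columns `wavelength`, `eps_hbo2`,
#'   `eps_hb` (cm^-1 M^-1); defaults to the embedded table.
#' @return Absorption coefficient in mm^-1.
#' @export
compute_absorption_coefficient <- function(blood_volume_fraction = 0.03,
                                           hb_concentration = 15,
                                           oxygen_saturation = 0.7,
                                           wavelength = 490,
                                           extinction_table = hemoglobin_extinction) {
  if (blood_volume_fraction < 0 || blood_volume_fraction > 1 ||
      oxygen_saturation < 0 || oxygen_saturation > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (hb_concentration <= 0) stop("hb_concentration must be > 0", call. = FALSE)
  rng <- range(extinction_table$wavelength)
  if (wavelength < rng[1] || wavelength > rng[2])
    stop("wavelength outside extinction table range", call. = FALSE)
  eps_hbo2 <- stats::approx(extinction_table$wavelength,
                            extinction_table$eps_hbo2, wavelength)$y
  eps_hb <- stats::approx(extinction_table$wavelength,
                          extinction_table$eps_hb, wavelength)$y
  eps_mix <- oxygen_saturation * eps_hbo2 + (1 - oxygen_saturation) * eps_hb
  conc_molar <- hb_concentration * 10 / 64500   # g/dL -> g/L -> mol/L
  mu_a_cm <- blood_volume_fraction * log(10) * eps_mix * conc_molar
  mu_a_cm / 10                                  # cm^-1 -> mm^-1
}

#' Voxel grid specification
#'
#' Isotropic voxel grid holding the fluence field. The fiber tip sits at the
#' grid center; the default is the 1-mm cube of 5-um voxels (200^3).
#'
#' @param extent Edge length(s) of the grid in mm (length 1 or 3).
#' @param voxel_size Voxel edge in mm (default 0.005).
#' @return An object of class `voxel_grid` with fields `dims`, `voxel_size`,
#'   `extent` and `origin` (the low corner, tip-centered convention).
#' @export
voxel_grid <- function(extent = 1, voxel_size = 0.005) {
  if (voxel_size <= 0) stop("voxel_size must be > 0", call. = FALSE)
  extent <- rep_len(extent, 3L)
  dims <- round(extent / voxel_size)
  if (any(dims < 1)) stop("grid must be at least one voxel per axis",
                          call. = FALSE)
  extent <- dims * voxel_size   # exact by construction
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 extent = extent, origin = -extent / 2),
            class = "voxel_grid")
}

#' Photon launch specification for a fiber tip
#'
#' @param numerical_aperture Fiber NA (default 0.377). The polar launch
#'   angle is drawn as `|N(0, sigma^2)|` truncated at pi/2 with
#'   `sigma = asin(NA / n_medium)`.
#' @param core_diameter Fiber core diameter in mm (default 0.0051); launch
#'   positions are uniform over the core face.
#' @param tip Tip position, mm (3-vector; default grid center at origin).
#' @param axis Unit fiber axis (default +z, the only supported axis).
#' @return An object of class `launch_spec`.
#' @export
launch_spec <- function(numerical_aperture = 0.377, core_diameter = 0.0051,
                        tip = c(0, 0, 0), axis = c(0, 0, 1)) {
  if (core_diameter <= 0) stop("core_diameter must be > 0", call. = FALSE)
  if (numerical_aperture < 0)
    stop("numerical_aperture must be >= 0", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  if (max(abs(axis - c(0, 0, 1))) > 1e-12)
    stop("only the +z fiber axis is supported", call. = FALSE)
  structure(list(numerical_aperture = numerical_aperture,
                 core_diameter = core_diameter,
                 tip = as.numeric(tip), axis = axis),
            class = "launch_spec")
}
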