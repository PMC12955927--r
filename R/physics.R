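#' Boltzmann constant (J/K)
#' @export
kB <- 1.380649e-23

#' Stokes-Einstein diffusion coefficient from hydrodynamic diameter
#'
#' `D = kB * T / (3 * pi * eta * d)` for a sphere of hydrodynamic diameter
#' `d` in a medium of viscosity `eta` at absolute temperature `T`. Strictly
#' decreasing in diameter.
#'
#' @param diameter_m hydrodynamic diameter (m).
#' @param temperature_k absolute temperature (K); default water at 25 C.
#' @param viscosity_pa_s dynamic viscosity (Pa s); default 8.9e-4.
#' @return diffusion coefficient (m^2/s).
#' @examples
#' diffusion_coefficient_from_diameter(90e-9) # ~5.45e-12 m^2/s
#' @export
diffusion_coefficient_from_diameter <- function(diameter_m,
                                                temperature_k = 298.15,
                                                viscosity_pa_s = 8.9e-4) {
  if (any(!is.finite(diameter_m)) || any(diameter_m <= 0)) {
    stop("diffusion_coefficient_from_diameter: diameter must be > 0")
  }
  if (temperature_k <= 0 || viscosity_pa_s <= 0) {
    stop("diffusion_coefficient_from_diameter: temperature and viscosity must be > 0")
  }
  kB * temperature_k / (3 * pi * viscosity_pa_s * diameter_m)
}

#' Hydrodynamic diameter from diffusion coefficient (inverse Stokes-Einstein)
#' @param d_m2_s diffusion coefficient (m^2/s).
#' @inheritParams diffusion_coefficient_from_diameter
#' @return hydrodynamic diameter (m).
#' @export
diameter_from_diffusion_coefficient <- function(d_m2_s,
                                                temperature_k = 298.15,
                                                viscosity_pa_s = 8.9e-4) {
  if (any(!is.finite(d_m2_s)) || any(d_m2_s <= 0)) {
    stop("diameter_from_diffusion_coefficient: D must be > 0")
  }
  kB * temperature_k / (3 * pi * viscosity_pa_s * d_m2_s)
}

#' Lateral focal transit (diffusion) time
#'
#' `tau_D = omega_xy^2 / (4 D)`: the mean dwell time of a diffuser with
#' coefficient `D` inside the lateral 1/e^2 beam waist `omega_xy`.
#'
#' @param d_m2_s diffusion coefficient (m^2/s).
#' @param waist_xy_m lateral 1/e^2 beam waist (m).
#' @return transit time (s).
#' @export
diffusion_time <- function(d_m2_s, waist_xy_m) {
  if (any(d_m2_s <= 0) || any(waist_xy_m <= 0)) {
    stop("diffusion_time: inputs must be > 0")
  }
  waist_xy_m^2 / (4 * d_m2_s)
}

#' Effective single-color confocal detection volume
#'
#' `V_eff = pi^(3/2) * omega_xy^2 * omega_z` for a 3D Gaussian detection
#' profile; the occupancy N read from a correlation amplitude refers to this
#' volume.
#'
#' @param waist_xy_m lateral 1/e^2 waist (m).
#' @param waist_z_m axial 1/e^2 extent (m).
#' @return volume (m^3).
#' @export
effective_volume <- function(waist_xy_m, waist_z_m) {
  pi^(3 / 2) * waist_xy_m^2 * waist_z_m
}

#' Effective two-color overlap volume
#'
#' The cross-correlation amplitude of a dual-labeled species refers to the
#' overlap volume of the two Gaussian detection profiles,
#' `V_rg = pi^(3/2) * ((wg^2+wr^2)/2) * sqrt((wzg^2+wzr^2)/2)`, further
#' reduced by `exp(-2 dz^2 / (wzg^2 + wzr^2))` when the foci are axially
#' offset by `dz`.
#'
#' @param waist_xy_g,waist_z_g green lateral/axial waists (m).
#' @param waist_xy_r,waist_z_r red lateral/axial waists (m).
#' @param axial_offset_m axial focus shift between the colors (m).
#' @return list with `volume` (m^3) and `offset_factor` (dimensionless
#'   amplitude attenuation from the axial offset).
#' @export
overlap_volume <- function(waist_xy_g, waist_z_g, waist_xy_r, waist_z_r,
                           axial_offset_m = 0) {
  wxy2 <- (waist_xy_g^2 + waist_xy_r^2) / 2
  wz2 <- (waist_z_g^2 + waist_z_r^2) / 2
  off <- exp(-2 * axial_offset_m^2 / (waist_z_g^2 + waist_z_r^2))
  list(volume = pi^(3 / 2) * wxy2 * sqrt(wz2), offset_factor = off)
}
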