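#' Pore-permeation model parameters
#'
#' Geometry and physical conditions for hindered diffusion of a spherical
#' particle through the cylindrical pores of the diaphragmed fenestrae of the
#' choriocapillaris endothelium. The default geometry (pore diameter in the
#' reported 6-12 nm range, ~30 nm effective pore length, 14 pores per
#' diaphragm, 3e7 fenestrae/mm^2) is a calibration set chosen once to land the
#' ApoA-I-Ch permeability near its tabulated value; the downstream flux model
#' always uses the tabulated constant, and this module serves to rationalise
#' it and to demonstrate size exclusion of the larger lipoprotein particles.
#'
#' @param particle_diameter Particle diameter, nm (ApoA-I-Ch 6.3; LDL 21;
#'   ApoB-Ch 70).
#' @param pore_diameter Pore diameter, nm.
#' @param pore_length Effective pore (diaphragm) length, nm.
#' @param pores_per_fenestra Pores per fenestral diaphragm.
#' @param fenestra_density Fenestrae per mm^2 of endothelium.
#' @param temperature Absolute temperature, K.
#' @param solvent_viscosity Solvent viscosity, Pa s (water at 37 C).
#' @return An object of class `pore_model_params`.
#' @export
pore_model_params <- function(particle_diameter = 6.3,
                              pore_diameter = 10,
                              pore_length = 30,
                              pores_per_fenestra = 14,
                              fenestra_density = 3e7,
                              temperature = 310,
                              solvent_viscosity = 6.9e-4) {
  stopifnot(particle_diameter > 0, pore_diameter > 0, pore_length > 0,
            pores_per_fenestra > 0, fenestra_density > 0,
            temperature > 0, solvent_viscosity > 0)
  structure(
    list(particle_diameter = particle_diameter,
         pore_diameter = pore_diameter,
         pore_length = pore_length,
         pores_per_fenestra = pores_per_fenestra,
         fenestra_density = fenestra_density,
         temperature = temperature,
         solvent_viscosity = solvent_viscosity),
    class = "pore_model_params"
  )
}

#' Stokes-Einstein diffusivity of a spherical particle
#'
#' `D = kB * T / (3 * pi * eta * d)` for a sphere of diameter `d`.
#'
#' @param d Particle diameter, nm.
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Free diffusion coefficient in cm^2/s.
#' @examples
#' stokes_einstein_diffusivity(6.3)  # ~1.0e-6 cm^2/s
#' @export
stokes_einstein_diffusivity <- function(d, temperature = 310,
                                        viscosity = 6.9e-4) {
  stopifnot(all(d > 0), temperature > 0, viscosity > 0)
  kB <- 1.380649e-23                       # J/K
  d_m <- d * 1e-9
  D_m2_s <- kB * temperature / (3 * pi * viscosity * d_m)
  D_m2_s * 1e4                             # m^2/s -> cm^2/s
}

#' Renkin centerline hindrance factor for a cylindrical pore
#'
#' For a particle-to-pore diameter ratio `lam < 1` returns the classical
#' steric-plus-hydrodynamic hindrance
#' `H = (1 - lam)^2 * (1 - 2.104 lam + 2.09 lam^3 - 0.95 lam^5)`;
#' particles as large as the pore or larger are fully excluded (`H = 0`).
#' `H` decreases monotonically from 1 at `lam = 0` to 0 at `lam = 1`.
#'
#' @param lam Particle/pore diameter ratio (>= 0), vectorised.
#' @return Hindrance factor in \[0, 1\].
#' @export
renkin_hindrance <- function(lam) {
  stopifnot(all(lam >= 0))
  h <- (1 - lam)^2 * (1 - 2.104 * lam + 2.09 * lam^3 - 0.95 * lam^5)
  h[lam >= 1] <- 0
  pmax(h, 0)
}

#' Effective permeability of the fenestrated endothelium to a particle
#'
#' Combines free diffusion, Renkin hindrance and the open pore area fraction:
#' `P = D * H(lam) * eps / L`, where `eps = fenestra_density *
#' pores_per_fenestra * pore cross-section` is the areal fraction of the
#' endothelium open as pores and `L` is the effective pore length. Particles
#' at or above the pore size are size-excluded (`P = 0`).
#'
#' @param params A [pore_model_params()] object.
#' @return A list with `diffusivity` (cm^2/s), `lambda`, `hindrance`,
#'   `open_area_fraction`, `permeability` (cm/s) and `size_excluded`
#'   (logical).
#' @examples
#' fenestra_permeability(pore_model_params())$permeability       # ~1.6e-4
#' fenestra_permeability(pore_model_params(21))$size_excluded    # TRUE (LDL)
#' @export
fenestra_permeability <- function(params) {
  stopifnot(inherits(params, "pore_model_params"))
  lam <- params$particle_diameter / params$pore_diameter
  D <- stokes_einstein_diffusivity(params$particle_diameter,
                                   params$temperature,
                                   params$solvent_viscosity)
  pore_area_mm2 <- pi * (params$pore_diameter / 2 * 1e-6)^2  # nm -> mm
  eps <- params$fenestra_density * params$pores_per_fenestra * pore_area_mm2
  H <- renkin_hindrance(lam)
  L_cm <- params$pore_length * 1e-7
  list(diffusivity = D,
       lambda = lam,
       hindrance = H,
       open_area_fraction = eps,
       permeability = D * H * eps / L_cm,
       size_excluded = lam >= 1)
}
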