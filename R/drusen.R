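#' Parameters of basal RPE cholesterol efflux and drusen deposition
#'
#' Cholesterol leaves the basal RPE by two routes: ABCA1-mediated efflux to
#' lipid-poor ApoA-I (small ~6.3 nm particles that clear through the
#' choriocapillaris fenestrae) and secretion of large (~70 nm) ApoB-Ch
#' particles that cannot cross the fenestrae and accumulate in Bruch's
#' membrane as basal linear deposits and drusen.
#'
#' @param kin_abca1 Apical ABCA1 delivery flux, pg/mm^2/min.
#' @param apical_basal_ratio Apical:basal ABCA1 expression ratio (> 1).
#' @param hepatic_apob_flux ApoB-Ch efflux if RPE secretion matched the
#'   hepatocyte, pg/mm^2/min.
#' @param apob_expr_frac,mtp_expr_frac RPE:liver mRNA expression fractions of
#'   ApoB and MTP-A, in (0, 1].
#' @param p_apoai_cc Permeability of ApoA-I-Ch particles across the CC, cm/s.
#' @param ch_to_apoai_mass_ratio Ch:ApoA-I mass ratio of the nascent particle.
#' @param deposit_ch_density Volumetric Ch density of the deposited drusen
#'   material, pg/mm^3; defaults to the growth-rate calibration of
#'   [deposit_density_from_growth_calibration()].
#' @return An object of class `efflux_params`.
#' @export
efflux_params <- function(kin_abca1 = 6.73,
                          apical_basal_ratio = 6.37,
                          hepatic_apob_flux = 967,
                          apob_expr_frac = 0.075,
                          mtp_expr_frac = 0.04,
                          p_apoai_cc = 1.2e-4,
                          ch_to_apoai_mass_ratio = 0.14,
                          deposit_ch_density =
                            deposit_density_from_growth_calibration(1, 0.7)) {
  stopifnot(kin_abca1 > 0, apical_basal_ratio > 1,
            hepatic_apob_flux > 0,
            apob_expr_frac > 0, apob_expr_frac <= 1,
            mtp_expr_frac > 0, mtp_expr_frac <= 1,
            p_apoai_cc > 0, ch_to_apoai_mass_ratio > 0,
            deposit_ch_density > 0)
  structure(
    list(kin_abca1 = kin_abca1, apical_basal_ratio = apical_basal_ratio,
         hepatic_apob_flux = hepatic_apob_flux,
         apob_expr_frac = apob_expr_frac, mtp_expr_frac = mtp_expr_frac,
         p_apoai_cc = p_apoai_cc,
         ch_to_apoai_mass_ratio = ch_to_apoai_mass_ratio,
         deposit_ch_density = deposit_ch_density),
    class = "efflux_params"
  )
}

#' Macrophage drusen-clearance parameters
#'
#' Macrophages infiltrating Bruch's membrane ingest drusen Ch and efflux it
#' via ABCA1 to lipid-poor ApoA-I, modelled as Michaelis-Menten in the local
#' ApoA-I concentration with per-cell capacity `vmax_per_cell`.
#'
#' @param vmax_per_cell Maximum ABCA1 efflux per macrophage, pg/cell/min.
#' @param km_apoai Michaelis constant, as ApoA-I concentration in ug/ml.
#' @param density Macrophage density, cells/mm^2 (>= 0).
#' @param c_apoai_brm Lipid-poor ApoA-I concentration near the drusen, ug/ml.
#' @param saturating_apoai If `TRUE`, the ApoA-I Michaelis factor is taken as
#'   1 (saturating ApoA-I limit).
#' @return An object of class `macrophage_params`.
#' @export
macrophage_params <- function(vmax_per_cell = 5.79e-2,
                              km_apoai = 5,
                              density = 1000,
                              c_apoai_brm = 25,
                              saturating_apoai = FALSE) {
  stopifnot(vmax_per_cell > 0, km_apoai > 0, density >= 0, c_apoai_brm > 0,
            is.logical(saturating_apoai))
  structure(
    list(vmax_per_cell = vmax_per_cell, km_apoai = km_apoai,
         density = density, c_apoai_brm = c_apoai_brm,
         saturating_apoai = saturating_apoai),
    class = "macrophage_params"
  )
}

#' ABCA1-mediated Ch efflux from the basal RPE surface
#'
#' Scales the apical ABCA1 delivery flux down by the apical:basal expression
#' ratio.
#'
#' @param kin_abca1 Apical ABCA1 flux, pg/mm^2/min.
#' @param apical_basal_ratio Apical:basal ABCA1 expression ratio.
#' @return Basal efflux flux in pg/mm^2/min.
#' @examples
#' basal_abca1_flux(6.73, 6.37)  # 1.06
#' @export
basal_abca1_flux <- function(kin_abca1, apical_basal_ratio) {
  stopifnot(kin_abca1 > 0, apical_basal_ratio > 0)
  kin_abca1 / apical_basal_ratio
}

#' ApoB-Ch particle secretion flux from the RPE
#'
#' The hepatocyte-equivalent secretion flux scaled by the RPE's relative
#' ApoB and MTP-A expression.
#'
#' @param hepatic_flux Hepatocyte-equivalent ApoB-Ch flux, pg/mm^2/min.
#' @param apob_expr_frac,mtp_expr_frac Relative expression fractions.
#' @return ApoB-Ch efflux flux in pg/mm^2/min.
#' @examples
#' apob_ch_flux(967, 0.075, 0.04)  # 2.90, quoted as ~3
#' @export
apob_ch_flux <- function(hepatic_flux, apob_expr_frac, mtp_expr_frac) {
  stopifnot(hepatic_flux >= 0,
            apob_expr_frac > 0, apob_expr_frac <= 1,
            mtp_expr_frac > 0, mtp_expr_frac <= 1)
  hepatic_flux * apob_expr_frac * mtp_expr_frac
}

#' Steady-state ApoA-I-Ch concentration in Bruch's membrane
#'
#' A constant ApoA-I-Ch efflux into BrM balanced by clearance through the CC
#' fenestrae sets the steady-state concentration `C = flux / (P * k)`, with
#' `k` the permeability-to-flux coefficient ([flux_coefficient()]). The
#' ApoA-I protein concentration follows from the particle's Ch:ApoA-I mass
#' ratio.
#'
#' @param flux ApoA-I-Ch efflux flux (as Ch mass), pg/mm^2/min.
#' @param p_apoai_cc CC permeability of the particles, cm/s.
#' @param ch_to_apoai_mass_ratio Ch:ApoA-I mass ratio.
#' @return A list with `ch_conc` and `apoai_conc`, both in mg/dl.
#' @examples
#' apoai_ch_concentration(1, 1.2e-4, 0.14)$ch_conc  # 0.0014 mg Ch/dl
#' @export
apoai_ch_concentration <- function(flux, p_apoai_cc = 1.2e-4,
                                   ch_to_apoai_mass_ratio = 0.14) {
  stopifnot(flux >= 0, p_apoai_cc > 0, ch_to_apoai_mass_ratio > 0)
  ch <- flux / (p_apoai_cc * flux_coefficient())
  list(ch_conc = ch, apoai_conc = ch / ch_to_apoai_mass_ratio)
}

#' Calibrate the volumetric Ch density of deposited drusen material
#'
#' The linear growth model converts an ApoB-Ch deposition flux into a
#' thickness growth rate through the deposit's Ch density:
#' `dh/dt = flux / rho`. Anchoring at a reference flux and its growth rate
#' gives `rho = flux * (min/year) / growth`, independent of the anchor chosen
#' on the proportional relation.
#'
#' @param reference_flux Anchor ApoB-Ch flux, pg/mm^2/min.
#' @param reference_growth Growth rate at the anchor flux, um/year.
#' @return Deposit Ch density in pg/mm^3.
#' @examples
#' deposit_density_from_growth_calibration(1, 0.7)  # 7.51e8 (~0.75 g/cm^3)
#' @export
deposit_density_from_growth_calibration <- function(reference_flux = 1,
                                                    reference_growth = 0.7) {
  stopifnot(reference_flux > 0, reference_growth > 0)
  growth_mm_per_year <- reference_growth * 1e-3
  reference_flux * minutes_per_year() / growth_mm_per_year
}

#' Drusen thickness growth rate from the ApoB-Ch deposition flux
#'
#' @param apob_flux ApoB-Ch deposition flux, pg/mm^2/min (>= 0).
#' @param deposit_ch_density Deposit Ch density, pg/mm^3.
#' @return Growth rate in um/year, proportional to the flux.
#' @examples
#' rho <- deposit_density_from_growth_calibration(1, 0.7)
#' drusen_growth_rate(6, rho)  # 4.2 um/year
#' @export
drusen_growth_rate <- function(apob_flux, deposit_ch_density =
                                 deposit_density_from_growth_calibration()) {
  stopifnot(all(apob_flux >= 0), deposit_ch_density > 0)
  apob_flux * minutes_per_year() / deposit_ch_density * 1e3
}

#' Drusen height after linear growth
#'
#' @param rate Growth rate, um/year (>= 0).
#' @param years Elapsed time in years (>= 0).
#' @return Height in um (`rate * years`; includes basal linear deposit).
#' @export
drusen_height <- function(rate, years) {
  stopifnot(all(rate >= 0), all(years >= 0))
  rate * years
}

#' Macrophage-mediated drusen Ch clearance flux
#'
#' Total areal clearance flux `density * vmax_per_cell * s`, where `s` is the
#' ApoA-I Michaelis saturation factor `C/(Km + C)` (or 1 in the saturating
#' limit).
#'
#' @param mac A [macrophage_params()] object.
#' @return Clearance flux in pg/mm^2/min.
#' @export
macrophage_clearance_flux <- function(mac) {
  stopifnot(inherits(mac, "macrophage_params"))
  s <- if (mac$saturating_apoai) 1 else
    mac$c_apoai_brm / (mac$km_apoai + mac$c_apoai_brm)
  mac$density * mac$vmax_per_cell * s
}

#' Time course of drusen height under macrophage clearance
#'
#' Linear clearance-only (optionally with concurrent ApoB-Ch deposition)
#' dynamics: `dh/dt = (deposition - clearance) / rho`, with the height floored
#' at zero once the druse is cleared.
#'
#' @param h0 Initial drusen height, um (>= 0).
#' @param mac A [macrophage_params()] object.
#' @param efflux An [efflux_params()] object (supplies the deposit density
#'   and, when `include_deposition = TRUE`, the ApoB-Ch deposition flux).
#' @param include_deposition Include ongoing ApoB-Ch deposition? Default
#'   `FALSE` (clearance-only).
#' @param horizon_years Simulation horizon in years.
#' @param n_points Number of time points in the returned trajectory.
#' @return An object of class `drusen_trajectory`: list with `times` (min),
#'   `heights` (um), `time_to_clear` (min, or `NA` if the druse never
#'   clears), and `net_rate` (um/year; negative while shrinking).
#' @export
drusen_clearance_timecourse <- function(h0, mac, efflux = efflux_params(),
                                        include_deposition = FALSE,
                                        horizon_years = 10,
                                        n_points = 201) {
  stopifnot(h0 >= 0, inherits(mac, "macrophage_params"),
            inherits(efflux, "efflux_params"), horizon_years > 0,
            n_points >= 2)
  deposition <- if (include_deposition) {
    apob_ch_flux(efflux$hepatic_apob_flux, efflux$apob_expr_frac,
                 efflux$mtp_expr_frac)
  } else 0
  net_flux <- deposition - macrophage_clearance_flux(mac)  # pg/mm^2/min
  rho <- efflux$deposit_ch_density
  net_rate_um_min <- net_flux / rho * 1e3
  times <- seq(0, horizon_years * minutes_per_year(), length.out = n_points)
  heights <- pmax(0, h0 + net_rate_um_min * times)
  time_to_clear <- if (net_rate_um_min < 0 && h0 > 0) {
    h0 / (-net_rate_um_min)
  } else if (h0 == 0) 0 else NA_real_
  structure(
    list(times = times, heights = heights, time_to_clear = time_to_clear,
         net_rate = net_rate_um_min * minutes_per_year()),
    class = "drusen_trajectory"
  )
}

#' Macrophage density required to clear a druse in a given time
#'
#' Inverts the clearance-only linear model:
#' `density = h0 * rho / (t_clear * vmax_per_cell * s)`, the exact inverse of
#' [drusen_clearance_timecourse()] in the no-deposition case.
#'
#' @param h0 Initial drusen height, um (> 0).
#' @param t_clear Target clearance time, min (> 0).
#' @param mac A [macrophage_params()] object (its `density` field is ignored;
#'   `vmax_per_cell` and the ApoA-I saturation convention are used).
#' @param efflux An [efflux_params()] object (supplies the deposit density).
#' @return Required density in cells/mm^2.
#' @examples
#' mac <- macrophage_params(saturating_apoai = TRUE)
#' required_macrophage_density(120, 10 * minutes_per_month(), mac)  # ~3550
#' @export
required_macrophage_density <- function(h0, t_clear, mac,
                                        efflux = efflux_params()) {
  stopifnot(h0 > 0, t_clear > 0, inherits(mac, "macrophage_params"),
            inherits(efflux, "efflux_params"))
  s <- if (mac$saturating_apoai) 1 else
    mac$c_apoai_brm / (mac$km_apoai + mac$c_apoai_brm)
  h0_mm <- h0 * 1e-3
  h0_mm * efflux$deposit_ch_density / (t_clear * mac$vmax_per_cell * s)
}
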