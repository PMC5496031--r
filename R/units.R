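#' Unit system and conversions
#'
#' The model works internally in a canonical unit system of mass in picograms
#' (pg), length in millimetres (mm) and time in minutes (min); concentrations
#' are carried internally as pg/mm^3 and presented at the interface in the
#' clinical units the quantities are usually quoted in (mg/dl for LDL
#' cholesterol, ug/ml for ApoA-I). All areal cholesterol fluxes are in
#' pg/mm^2/min.
#'
#' @name retchol-units
#' @keywords internal
NULL

# Conversion factors to the canonical concentration unit, pg/mm^3.
# 1 mg/dl = 10 ug/ml = 1e7 pg/cm^3 = 1e4 pg/mm^3.
.conc_to_pg_mm3 <- c(
  "mg/dl"   = 1e4,
  "ug/ml"   = 1e3,
  "pg/cm3"  = 1e-3,
  "pg/mm3"  = 1,
  "g/cm3"   = 1e9
)

#' Convert a concentration between supported units
#'
#' Exact dimensional conversion between the concentration units used across
#' the model's parameter tables: `"mg/dl"`, `"ug/ml"`, `"pg/cm3"`, `"pg/mm3"`
#' and `"g/cm3"`. Round trips are identities to machine precision.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Unit strings from the supported set.
#' @return Numeric vector of `value` expressed in `to`.
#' @examples
#' convert_concentration(1, "mg/dl", "pg/cm3")  # 1e7
#' convert_concentration(25, "ug/ml", "mg/dl")  # 2.5
#' @export
convert_concentration <- function(value, from, to) {
  for (u in c(from, to)) {
    if (!u %in% names(.conc_to_pg_mm3)) {
      stop("unsupported concentration unit: '", u, "' (supported: ",
           paste(names(.conc_to_pg_mm3), collapse = ", "), ")", call. = FALSE)
    }
  }
  value * .conc_to_pg_mm3[[from]] / .conc_to_pg_mm3[[to]]
}

#' Calendar and flux-coupling constants
#'
#' Calendar conventions used throughout: 1 year = 365 days = 525,600 min and
#' 1 month = 1/12 year = 43,800 min. `flux_coefficient()` is the factor that
#' turns a permeability in cm/s times a concentration in mg/dl into an areal
#' flux in pg/mm^2/min (1 cm/s = 600 mm/min and 1 mg/dl = 1e4 pg/mm^3, so the
#' factor is 6e6).
#'
#' @return The respective constant (numeric scalar).
#' @export
minutes_per_year <- function() 365 * 24 * 60

#' @rdname minutes_per_year
#' @export
minutes_per_month <- function() minutes_per_year() / 12

#' @rdname minutes_per_year
#' @export
minutes_per_day <- function() 24 * 60

#' @rdname minutes_per_year
#' @export
flux_coefficient <- function() {
  mm_per_min <- 10 * 60                                  # 1 cm/s in mm/min
  conc <- convert_concentration(1, "mg/dl", "pg/mm3")    # 1 mg/dl in pg/mm^3
  mm_per_min * conc
}

#' Areal flux driven by a permeability and a concentration
#'
#' Computes the passive flux `P * C` across a barrier with effective
#' permeability `P` (cm/s) exposed to a concentration `C` (mg/dl), expressed
#' in the model's canonical flux unit pg/mm^2/min. The result is bilinear in
#' both arguments.
#'
#' @param p_cm_s Permeability coefficient in cm/s (>= 0).
#' @param c_mg_dl Concentration in mg/dl (>= 0).
#' @return Flux in pg/mm^2/min.
#' @examples
#' permeability_flux(1.2e-7, 1)  # 0.72
#' @export
permeability_flux <- function(p_cm_s, c_mg_dl) {
  stopifnot(all(p_cm_s >= 0), all(c_mg_dl >= 0))
  p_cm_s * c_mg_dl * flux_coefficient()
}
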