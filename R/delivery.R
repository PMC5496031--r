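#' Parameters of LDL delivery from the choriocapillaris to the RPE
#'
#' LDL-cholesterol reaches the retinal pigment epithelium in three steps:
#' bidirectional transcytosis across the choriocapillaris (CC) endothelium
#' into Bruch's membrane (effective permeabilities `p_in_ldl` and
#' `pout_ratio * p_in_ldl`), saturable LDL-receptor uptake by the RPE
#' (Michaelis-Menten with `vmax_ldlr`, `km_ldlr`), and ABCA1-mediated
#' transport of Ch from the apical RPE surface to the outer retina
#' (constant flux `kin_abca1`).
#'
#' @param p_in_ldl Transcytosis permeability, lumen to BrM, cm/s.
#' @param pout_ratio `P_out/P_in`, dimensionless in (0, 1] (0 allowed as the
#'   no-backflux limit).
#' @param vmax_ldlr Maximum LDLR uptake flux, pg/mm^2/min.
#' @param km_ldlr Michaelis constant, as LDL-Ch concentration in mg/dl.
#' @param kin_abca1 Apical ABCA1 delivery flux, pg/mm^2/min.
#' @return An object of class `delivery_params`.
#' @export
delivery_params <- function(p_in_ldl = 1.2e-7,
                            pout_ratio = 1,
                            vmax_ldlr = 13.1,
                            km_ldlr = 5.4,
                            kin_abca1 = 6.73) {
  stopifnot(p_in_ldl > 0, pout_ratio >= 0, pout_ratio <= 1,
            vmax_ldlr > 0, km_ldlr > 0, kin_abca1 > 0)
  structure(
    list(p_in_ldl = p_in_ldl, pout_ratio = pout_ratio,
         vmax_ldlr = vmax_ldlr, km_ldlr = km_ldlr, kin_abca1 = kin_abca1),
    class = "delivery_params"
  )
}

#' LDLR-mediated Ch uptake flux at a given BrM LDL-Ch concentration
#'
#' Michaelis-Menten uptake `Vmax * C / (Km + C)`: monotone in `C` and
#' saturating at `Vmax`.
#'
#' @param c_brm LDL-Ch concentration in Bruch's membrane, mg/dl (>= 0).
#' @param params A [delivery_params()] object.
#' @return Uptake flux in pg/mm^2/min.
#' @export
ldlr_uptake_flux <- function(c_brm, params) {
  stopifnot(inherits(params, "delivery_params"), all(c_brm >= 0))
  params$vmax_ldlr * c_brm / (params$km_ldlr + c_brm)
}

#' Steady-state LDL-Ch level in Bruch's membrane and the resulting uptake
#'
#' Solves the steady-state mass balance of the BrM free-LDL pool,
#' `Pin * C_CC = Pout * C_BrM + Vmax * C_BrM / (Km + C_BrM)`
#' (all permeability terms converted to fluxes via [permeability_flux()]).
#' With `Pout > 0` this is a quadratic in `C_BrM` with exactly one positive
#' root, returned in closed form. With `Pout = 0` a steady state exists only
#' while the influx is below `Vmax`.
#'
#' @param c_cc LDL-Ch concentration in the choriocapillaris, mg/dl (>= 0).
#' @param params A [delivery_params()] object.
#' @return A list with `c_brm` (mg/dl) and `uptake_flux` (pg/mm^2/min).
#' @export
brm_ldl_steady_state <- function(c_cc, params) {
  stopifnot(inherits(params, "delivery_params"), c_cc >= 0)
  a <- params$p_in_ldl * flux_coefficient()          # influx per mg/dl of C_CC
  b <- a * params$pout_ratio                         # backflux per mg/dl of C_BrM
  vmax <- params$vmax_ldlr; km <- params$km_ldlr
  influx <- a * c_cc
  if (b == 0) {
    if (influx >= vmax) {
      stop("no steady state: with P_out = 0 the transcytotic influx (",
           signif(influx, 4), " pg/mm^2/min) meets or exceeds Vmax (",
           vmax, "); BrM LDL accumulates without bound", call. = FALSE)
    }
    c_brm <- influx * km / (vmax - influx)
  } else {
    # b*C^2 + (b*Km + Vmax - influx)*C - influx*Km = 0, positive root
    B <- b * km + vmax - influx
    c_brm <- (-B + sqrt(B^2 + 4 * b * influx * km)) / (2 * b)
  }
  list(c_brm = c_brm, uptake_flux = ldlr_uptake_flux(c_brm, params))
}

#' Choroidal LDL-Ch level giving 90% of the maximal RPE uptake
#'
#' At 90% saturation the BrM concentration is `9 * Km` by the Michaelis
#' relation; substituting into the steady-state balance gives, in closed form,
#' `C_CC = (Pout_flux(9 Km) + 0.9 Vmax) / a`, with `a` the influx coefficient
#' per mg/dl. The threshold increases with the backflux ratio and with `Km`.
#'
#' @param params A [delivery_params()] object.
#' @return Choriocapillaris LDL-Ch concentration in mg/dl.
#' @examples
#' c90_threshold(delivery_params(pout_ratio = 1))    # 65.0
#' c90_threshold(delivery_params(pout_ratio = 0.5))  # 40.7
#' @export
c90_threshold <- function(params) {
  stopifnot(inherits(params, "delivery_params"))
  a <- params$p_in_ldl * flux_coefficient()
  b <- a * params$pout_ratio
  (b * 9 * params$km_ldlr + 0.9 * params$vmax_ldlr) / a
}

#' Uptake curve over a grid of choroidal LDL-Ch concentrations
#'
#' Evaluates [brm_ldl_steady_state()] on a concentration grid for one or more
#' transcytosis backflux ratios.
#'
#' @param params A [delivery_params()] object.
#' @param c_cc_grid Non-negative, increasing vector of CC LDL-Ch levels,
#'   mg/dl.
#' @param pout_ratios Backflux ratios to evaluate; defaults to the one in
#'   `params`.
#' @return A data.frame with columns `pout_ratio`, `c_cc`, `c_brm`,
#'   `uptake_flux`.
#' @export
uptake_curve <- function(params, c_cc_grid,
                         pout_ratios = params$pout_ratio) {
  stopifnot(inherits(params, "delivery_params"),
            all(c_cc_grid >= 0), !is.unsorted(c_cc_grid, strictly = FALSE))
  rows <- lapply(pout_ratios, function(ratio) {
    p <- params; p$pout_ratio <- ratio
    ss <- lapply(c_cc_grid, brm_ldl_steady_state, params = p)
    data.frame(pout_ratio = ratio,
               c_cc = c_cc_grid,
               c_brm = vapply(ss, `[[`, numeric(1), "c_brm"),
               uptake_flux = vapply(ss, `[[`, numeric(1), "uptake_flux"))
  })
  do.call(rbind, rows)
}

#' ABCA1-mediated Ch delivery from the apical RPE to the outer retina
#'
#' A constant flux in this model; returned from the parameter set for
#' interface symmetry with the other delivery steps.
#'
#' @param params A [delivery_params()] object.
#' @return Flux in pg/mm^2/min.
#' @export
abca1_apical_delivery <- function(params) {
  stopifnot(inherits(params, "delivery_params"))
  params$kin_abca1
}
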