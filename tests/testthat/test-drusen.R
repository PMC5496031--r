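test_that("basal ABCA1 efflux scales the apical flux by the expression ratio", {
  expect_equal(basal_abca1_flux(6.73, 6.37), 1.06, tolerance = 5e-3)
  expect_equal(basal_abca1_flux(4.2, 1), 4.2)
  expect_equal(basal_abca1_flux(13.46, 6.37), 2 * basal_abca1_flux(6.73, 6.37))
})

test_that("ApoB-Ch secretion is the hepatic flux scaled by expression", {
  expect_equal(apob_ch_flux(967, 0.075, 0.04), 2.90, tolerance = 1e-3)
  expect_equal(apob_ch_flux(967, 1, 1), 967)
  expect_equal(apob_ch_flux(0, 0.075, 0.04), 0)
})

test_that("BrM ApoA-I-Ch concentrations match the permeability balance", {
  lo <- apoai_ch_concentration(1, 1.2e-4, 0.14)
  hi <- apoai_ch_concentration(6, 1.2e-4, 0.14)
  expect_equal(lo$ch_conc, 0.0014, tolerance = 1e-2)
  expect_equal(hi$ch_conc, 0.0084, tolerance = 1e-2)
  expect_equal(lo$apoai_conc, 0.01, tolerance = 1e-2)
  expect_equal(hi$apoai_conc, 0.06, tolerance = 1e-2)
  # exactness of the balance: C * P * k == flux
  expect_equal(permeability_flux(1.2e-4, lo$ch_conc), 1, tolerance = 1e-12)
})

test_that("deposit density calibration is scale invariant", {
  rho <- deposit_density_from_growth_calibration(1, 0.7)
  expect_equal(rho, 7.51e8, tolerance = 1e-3)
  expect_equal(deposit_density_from_growth_calibration(2, 1.4), rho)
  expect_equal(deposit_density_from_growth_calibration(6, 4.2), rho)
  # ~0.75 g/cm^3 in bulk units
  expect_equal(convert_concentration(rho, "pg/mm3", "g/cm3"), 0.751,
               tolerance = 1e-3)
})

test_that("drusen growth is linear in time and proportional to the flux", {
  rho <- deposit_density_from_growth_calibration(1, 0.7)
  expect_equal(drusen_growth_rate(1, rho), 0.7)
  expect_equal(drusen_growth_rate(6, rho), 4.2)
  expect_equal(drusen_growth_rate(0, rho), 0)
  fluxes <- c(0.5, 1, 2, 3, 6)
  expect_equal(drusen_growth_rate(fluxes, rho), fluxes * 0.7)
  expect_equal(drusen_height(4.2, 50), 210)
  expect_equal(drusen_height(0.7, 50), 35)
  expect_equal(drusen_height(2.1, 0), 0)
  yrs <- seq(0, 50, by = 10)
  expect_equal(drusen_height(4.2, yrs), 4.2 * yrs)
})

test_that("macrophage clearance flux combines density, capacity and ApoA-I", {
  base <- macrophage_params(density = 1000)
  expect_equal(macrophage_clearance_flux(base), 1000 * 0.0579 * 25 / 30)
  expect_equal(macrophage_clearance_flux(macrophage_params(density = 0)), 0)
  sat <- macrophage_params(density = 1000, saturating_apoai = TRUE)
  expect_equal(macrophage_clearance_flux(sat), 57.9)
})

test_that("clearance time courses reproduce the three density regimes", {
  efx <- efflux_params()
  sat1000 <- drusen_clearance_timecourse(
    120, macrophage_params(density = 1000, saturating_apoai = TRUE), efx)
  expect_equal(sat1000$time_to_clear / minutes_per_year(), 3,
               tolerance = 0.05)
  base500 <- drusen_clearance_timecourse(
    120, macrophage_params(density = 500), efx)
  expect_gt(base500$time_to_clear / minutes_per_year(), 5)
  base5000 <- drusen_clearance_timecourse(
    120, macrophage_params(density = 5000), efx)
  expect_lt(base5000$time_to_clear / minutes_per_year(), 1)
  # heights decrease linearly and are floored at zero
  expect_true(all(diff(sat1000$heights) <= 0))
  expect_equal(min(sat1000$heights), 0)
  expect_equal(sat1000$heights[1], 120)
})

test_that("clearance time scales inversely with density and capacity", {
  efx <- efflux_params()
  t_at <- function(density, vmax_fold = 1) {
    m <- macrophage_params(density = density,
                           vmax_per_cell = 5.79e-2 * vmax_fold)
    drusen_clearance_timecourse(120, m, efx)$time_to_clear
  }
  expect_equal(t_at(500) / t_at(1000), 2, tolerance = 1e-9)
  expect_equal(t_at(1000) / t_at(4000), 4, tolerance = 1e-9)
  expect_equal(t_at(1000, vmax_fold = 2), t_at(1000) / 2, tolerance = 1e-9)
})

test_that("clearance time decreases in ApoA-I and saturates at the limit", {
  efx <- efflux_params()
  t_at_apoai <- function(c) {
    drusen_clearance_timecourse(
      120, macrophage_params(density = 1000, c_apoai_brm = c), efx
    )$time_to_clear
  }
  cs <- c(1, 5, 25, 100, 1000, 1e6)
  ts <- vapply(cs, t_at_apoai, numeric(1))
  expect_true(all(diff(ts) < 0))
  t_sat <- drusen_clearance_timecourse(
    120, macrophage_params(density = 1000, saturating_apoai = TRUE), efx
  )$time_to_clear
  expect_equal(ts[length(ts)], t_sat, tolerance = 1e-4)
  expect_true(all(ts >= t_sat))
})

test_that("deposition can offset clearance and zero height clears at once", {
  efx <- efflux_params()
  weak <- macrophage_params(density = 10)  # clearance 0.48 < deposition 2.9
  growing <- drusen_clearance_timecourse(120, weak, efx,
                                         include_deposition = TRUE)
  expect_true(is.na(growing$time_to_clear))
  expect_gt(growing$net_rate, 0)
  none <- drusen_clearance_timecourse(0, macrophage_params(density = 1000),
                                      efx)
  expect_equal(none$time_to_clear, 0)
})

test_that("required density inverts the clearance time course exactly", {
  efx <- efflux_params()
  mac <- macrophage_params(saturating_apoai = TRUE)
  dens10mo <- required_macrophage_density(120, 10 * minutes_per_month(), mac,
                                          efx)
  expect_equal(dens10mo, 3500, tolerance = 0.05)
  # inverse proportionality in the target time
  expect_equal(required_macrophage_density(120, 20 * minutes_per_month(),
                                           mac, efx),
               dens10mo / 2, tolerance = 1e-12)
  # round trip: simulating at the returned density clears at the target time
  set.seed(11)
  for (i in 1:5) {
    h0 <- runif(1, 20, 300)
    t_target <- runif(1, 0.5, 8) * minutes_per_year()
    mac_i <- macrophage_params(c_apoai_brm = runif(1, 5, 100))
    d <- required_macrophage_density(h0, t_target, mac_i, efx)
    mac_i$density <- d
    tr <- drusen_clearance_timecourse(h0, mac_i, efx,
                                      horizon_years = 20)
    expect_equal(tr$time_to_clear, t_target, tolerance = 1e-9)
  }
})

test_that("cleared Ch mass per unit area equals height times density", {
  efx <- efflux_params()
  mac <- macrophage_params(density = 1000, saturating_apoai = TRUE)
  tr <- drusen_clearance_timecourse(120, mac, efx)
  cleared_mass <- macrophage_clearance_flux(mac) * tr$time_to_clear
  expect_equal(cleared_mass, 120e-3 * efx$deposit_ch_density,
               tolerance = 1e-9)
})
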