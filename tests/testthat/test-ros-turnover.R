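# Default chain with k_out calibrated to the 6-fold Ch decrease.
calibrated_chain <- function(f = 0) {
  ros_chain_params(k_out = calibrate_k_out(6, 0.85, 10), f_recycling = f)
}

test_that("k_out calibration inverts the geometric fold decrease", {
  expect_equal(calibrate_k_out(6, 0.85, 10), 0.187, tolerance = 2e-3)
  expect_equal(calibrate_k_out(1, 0.85, 10), 0)
  # doubling the number of steps while squaring the fold leaves k_out fixed
  expect_equal(calibrate_k_out(36, 0.85, 19), calibrate_k_out(6, 0.85, 10))
  expect_error(calibrate_k_out(0.5, 0.85, 10), "fold_decrease")
})

test_that("fold calibration round-trips through the steady-state profile", {
  for (fold in c(1.5, 3, 6, 20)) {
    p <- ros_chain_params(k_out = calibrate_k_out(fold, 0.85, 10))
    expect_equal(steady_state_profile(p)$fold_decrease, fold,
                 tolerance = 1e-9)
  }
})

test_that("disc Ch/PL ratio falls from 0.3 to ~0.05 along the chain", {
  # with the printed rounded k_out = 0.19: 0.3 * (0.85/1.04)^9 = 0.049
  ss_printed <- steady_state_profile(ros_chain_params(k_out = 0.19))
  expect_equal(ss_printed$ch_pl_ratio_profile[1], 0.3)
  expect_equal(ss_printed$ch_pl_ratio_profile[10], 0.049, tolerance = 2e-2)
  # with the calibrated k_out the 6-fold span is exact
  ss <- steady_state_profile(calibrated_chain())
  expect_equal(ss$ch_pl_ratio_profile[10], 0.05, tolerance = 1e-9)
  expect_true(all(diff(ss$ch_per_compartment) < 0))
})

test_that("steady-state fluxes conserve mass", {
  for (kout in c(0.05, 0.19, 0.4)) {
    p <- ros_chain_params(k_out = kout)
    ss <- steady_state_profile(p)
    expect_equal(ss$phagocytosis_flux + ss$pool_efflux_flux, p$j0_flux,
                 tolerance = 1e-9)
  }
  flat <- steady_state_profile(ros_chain_params(k_out = 0))
  expect_equal(flat$fold_decrease, 1)
  expect_equal(flat$pool_efflux_flux, 0)
  expect_equal(unique(flat$ch_per_compartment), 1)
})

test_that("turnover rate reproduces both tabulated anchors and is affine in f", {
  p <- calibrated_chain()
  expect_equal(turnover_rate(p, 0), 5.84)
  expect_equal(turnover_rate(p, 1), 5.84 / 6, tolerance = 1e-9)
  expect_equal(turnover_rate(p, 0.5), 5.84 * (1 - 0.5 * 5 / 6))
  # affine: the slope between any two points is constant
  f <- c(0, 0.25, 0.5, 0.75, 1)
  k <- turnover_rate(p, f)
  slopes <- diff(k) / diff(f)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-12)
  r <- (p$k_t / (p$k_t + p$k_out))^9
  expect_equal(slopes[1], -p$j0_flux * (1 - r))
  expect_error(turnover_rate(p, 1.2), "f_recycling")
})

test_that("ODE steady state matches the geometric closed form", {
  set.seed(1234)
  for (i in 1:5) {
    n <- sample(3:12, 1)
    kt <- runif(1, 0.3, 2)
    kout <- runif(1, 0, 1)
    p <- ros_chain_params(n_compartments = n,
                          discs_per_compartment = 100,
                          disc_influx_rate = 100 * kt,
                          k_t = kt, k_out = kout,
                          f_recycling = runif(1))
    traj <- simulate_chain(p, t_grid = c(0, 50 / kt, 100 / kt))
    final <- as.numeric(traj[nrow(traj), paste0("C", 1:n)])
    ss <- steady_state_profile(p)
    expect_equal(final / final[1], ss$ch_per_compartment, tolerance = 1e-6)
    # absolute anchor: C1 = J0/k_t (in pg/mm^2 with J0 per day)
    expect_equal(final[1], p$j0_flux * minutes_per_day() / kt,
                 tolerance = 1e-6)
    # steady-state external requirement matches the closed-form turnover
    expect_equal(traj$kin_ch[nrow(traj)], turnover_rate(p), tolerance = 1e-6)
  }
})

test_that("the steady state is a fixed point of the chain dynamics", {
  p <- calibrated_chain(f = 0.3)
  n <- p$n_compartments
  r <- p$k_t / (p$k_t + p$k_out)
  ss_state <- p$j0_flux * minutes_per_day() / p$k_t * r^(0:(n - 1))
  pool_rate <- 24
  pool_ss <- p$k_out * sum(ss_state[2:n]) / pool_rate
  traj <- simulate_chain(p, t_grid = seq(0, 30, by = 5),
                         initial_state = c(ss_state, pool_ss),
                         pool_rate = pool_rate)
  for (j in 1:n) {
    expect_equal(traj[[paste0("C", j)]],
                 rep(ss_state[j], nrow(traj)), tolerance = 1e-8)
  }
})

test_that("mean disc residence time is ~11 days at the default rates", {
  p <- ros_chain_params(k_out = 0)
  expect_equal(mean_transit_time(p), 10 / 0.85)
  # consistency with the simulated chain content: residence = content/influx
  traj <- simulate_chain(p, t_grid = c(0, 200, 400))
  content <- sum(traj[nrow(traj), paste0("C", 1:10)])
  influx_per_day <- p$j0_flux * minutes_per_day()
  expect_equal(content / influx_per_day, 10 / 0.85, tolerance = 1e-6)
})

test_that("inconsistent disc influx rate triggers the consistency warning", {
  expect_warning(ros_chain_params(disc_influx_rate = 40), "inconsistent")
  expect_silent(ros_chain_params())
})
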