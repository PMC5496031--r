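#' Transit-chain parameters for disc cholesterol in the rod outer segment
#'
#' The rod outer segment (ROS) is modelled as a chain of `n_compartments`
#' transit compartments (each holding `discs_per_compartment` discs). Discs
#' move down the chain with first-order rate constant `k_t` (per day) and lose
#' cholesterol from compartments 2..n with first-order rate constant `k_out`;
#' discs in the last compartment are phagocytosed by the retinal pigment
#' epithelium, also with rate constant `k_t`. Cholesterol leaving the discs
#' enters a recyclable pool from which a fraction `f_recycling` returns to the
#' rod inner segment for new disc formation, the rest being taken up by the
#' RPE. `j0_flux` anchors the total disc-Ch formation flux in pg/mm^2/min: it
#' equals the cholesterol turnover rate at zero recycling.
#'
#' @param n_compartments Number of transit compartments (>= 2).
#' @param discs_per_compartment Discs per compartment.
#' @param disc_influx_rate New-disc formation rate, discs/day.
#' @param k_t Disc transfer rate constant, 1/day.
#' @param k_out Disc Ch efflux rate constant (compartments 2..n), 1/day.
#' @param ch_pl_ratio_initial Ch/PL molar ratio of newly formed discs.
#' @param j0_flux Total disc-Ch formation flux, pg/mm^2/min.
#' @param f_recycling Fraction of pool Ch recycled to the RIS, in \[0, 1\].
#' @return An object of class `ros_chain_params`.
#' @export
ros_chain_params <- function(n_compartments = 10,
                             discs_per_compartment = 100,
                             disc_influx_rate = 85,
                             k_t = 0.85,
                             k_out = 0.19,
                             ch_pl_ratio_initial = 0.3,
                             j0_flux = 5.84,
                             f_recycling = 0) {
  stopifnot(n_compartments >= 2, k_t > 0, k_out >= 0,
            ch_pl_ratio_initial > 0, j0_flux >= 0)
  if (f_recycling < 0 || f_recycling > 1) {
    stop("f_recycling must lie in [0, 1] (got ", f_recycling, ")",
         call. = FALSE)
  }
  implied_kt <- disc_influx_rate / discs_per_compartment
  if (abs(implied_kt - k_t) > 1e-8 * max(1, k_t)) {
    warning("k_t (", k_t, "/day) is inconsistent with disc_influx_rate/",
            "discs_per_compartment (", implied_kt, "/day)", call. = FALSE)
  }
  structure(
    list(n_compartments = as.integer(n_compartments),
         discs_per_compartment = as.integer(discs_per_compartment),
         disc_influx_rate = disc_influx_rate,
         k_t = k_t, k_out = k_out,
         ch_pl_ratio_initial = ch_pl_ratio_initial,
         j0_flux = j0_flux, f_recycling = f_recycling),
    class = "ros_chain_params"
  )
}

#' Calibrate the disc Ch efflux constant to a stated fold decrease
#'
#' At steady state, each transit step past the first multiplies the disc Ch
#' content by `k_t / (k_t + k_out)`, so the Ch content falls
#' `(1 + k_out/k_t)^(n-1)`-fold from compartment 1 to compartment n. Given an
#' observed fold decrease this inverts to
#' `k_out = k_t * (fold^(1/(n-1)) - 1)`.
#'
#' @param fold_decrease Target compartment-1:compartment-n Ch ratio (>= 1).
#' @param k_t Disc transfer rate constant, 1/day.
#' @param n_compartments Chain length.
#' @return `k_out` in 1/day.
#' @examples
#' calibrate_k_out(6, 0.85, 10)  # 0.1872, printed rounded as 0.19
#' @export
calibrate_k_out <- function(fold_decrease, k_t, n_compartments) {
  stopifnot(k_t > 0, n_compartments >= 2)
  if (fold_decrease < 1) {
    stop("fold_decrease must be >= 1: disc Ch cannot increase down the chain",
         call. = FALSE)
  }
  k_t * (fold_decrease^(1 / (n_compartments - 1)) - 1)
}

#' Steady-state disc cholesterol profile of the transit chain
#'
#' Returns the closed-form steady state of the chain: the relative Ch content
#' per compartment follows a geometric profile with step ratio
#' `k_t / (k_t + k_out)` (the efflux applies to compartments 2..n only), the
#' Ch/PL molar ratio scales that profile to `ch_pl_ratio_initial` in
#' compartment 1, and the disc-formation flux `j0_flux` splits into the
#' phagocytosis flux leaving the last compartment and the efflux into the
#' recyclable pool.
#'
#' @param params A [ros_chain_params()] object.
#' @return An object of class `ros_steady_state`: list with
#'   `ch_per_compartment` (relative to compartment 1), `ch_pl_ratio_profile`,
#'   `fold_decrease`, `phagocytosis_flux`, `pool_efflux_flux` and `kin_ch`
#'   (all fluxes in pg/mm^2/min).
#' @export
steady_state_profile <- function(params) {
  stopifnot(inherits(params, "ros_chain_params"))
  n <- params$n_compartments
  r <- params$k_t / (params$k_t + params$k_out)
  rel <- r^(0:(n - 1))
  phag <- params$j0_flux * r^(n - 1)
  pool <- params$j0_flux - phag
  structure(
    list(ch_per_compartment = rel,
         ch_pl_ratio_profile = params$ch_pl_ratio_initial * rel,
         fold_decrease = rel[1] / rel[n],
         phagocytosis_flux = phag,
         pool_efflux_flux = pool,
         kin_ch = params$j0_flux - params$f_recycling * pool),
    class = "ros_steady_state"
  )
}

#' Steady-state cholesterol turnover rate of the outer retina
#'
#' The turnover rate is the external Ch influx into the rod inner segment
#' needed to sustain disc formation. Of the disc-formation flux `j0`, the
#' fraction reaching phagocytosis is `r = (k_t/(k_t + k_out))^(n-1)`; the rest
#' enters the recyclable pool, of which the recycled fraction `f` returns and
#' need not be supplied externally:
#' `Kin_Ch = j0 * (1 - f * (1 - r))`, an affine, decreasing function of `f`.
#'
#' @param params A [ros_chain_params()] object.
#' @param f_recycling Optional override of the recycling fraction.
#' @return Turnover flux in pg/mm^2/min.
#' @examples
#' p <- ros_chain_params(k_out = calibrate_k_out(6, 0.85, 10))
#' turnover_rate(p, f_recycling = 0)  # 5.84
#' turnover_rate(p, f_recycling = 1)  # 5.84/6 = 0.973
#' @export
turnover_rate <- function(params, f_recycling = params$f_recycling) {
  stopifnot(inherits(params, "ros_chain_params"))
  if (any(f_recycling < 0 | f_recycling > 1)) {
    stop("f_recycling must lie in [0, 1]", call. = FALSE)
  }
  r <- (params$k_t / (params$k_t + params$k_out))^(params$n_compartments - 1)
  params$j0_flux * (1 - f_recycling * (1 - r))
}

#' Time-dependent simulation of the disc transit chain
#'
#' Integrates the chain ODEs
#' `dC_1/dt = J0 - k_t C_1` and
#' `dC_i/dt = k_t C_{i-1} - (k_t + k_out) C_i` (i = 2..n),
#' where `C_i` is the areal Ch content of compartment i (pg/mm^2) and the
#' disc-formation flux `J0` is held fixed (disc formation proceeds at
#' `Kin_discs` regardless of where its cholesterol comes from). A recyclable
#' pool compartment collects `k_out * sum(C_2..C_n)` and drains with rate
#' constant `pool_rate`, its outflow split between recycling to the RIS
#' (fraction `f_recycling`, which offsets the external Ch requirement) and
#' uptake by the RPE. Because only the ratio `f_recycling` is identifiable at
#' steady state, `pool_rate` is an arbitrary documented time-scale and
#' pool-transient quantities should not be over-interpreted.
#'
#' @param params A [ros_chain_params()] object.
#' @param t_grid Increasing vector of times, in days.
#' @param initial_state Optional non-negative vector of length
#'   `n_compartments + 1` (compartments then pool), pg/mm^2. Defaults to all
#'   zeros.
#' @param pool_rate Pool drainage rate constant, 1/day.
#' @return A data.frame with columns `time` (days), `C1..Cn`, `pool`
#'   (pg/mm^2), `phagocytosis_flux`, `pool_efflux_flux`, `kin_ch`
#'   (pg/mm^2/min).
#' @export
simulate_chain <- function(params, t_grid, initial_state = NULL,
                           pool_rate = 24) {
  stopifnot(inherits(params, "ros_chain_params"),
            length(t_grid) >= 2, all(diff(t_grid) > 0), all(t_grid >= 0))
  n <- params$n_compartments
  if (is.null(initial_state)) initial_state <- numeric(n + 1)
  stopifnot(length(initial_state) == n + 1, all(initial_state >= 0))
  j0_day <- params$j0_flux * minutes_per_day()  # pg/mm^2/day
  kt <- params$k_t; ko <- params$k_out; f <- params$f_recycling

  rhs <- function(t, y, parms) {
    C <- y[1:n]; P <- y[n + 1]
    dC <- numeric(n)
    dC[1] <- j0_day - kt * C[1]
    if (n >= 2) {
      dC[2:n] <- kt * C[1:(n - 1)] - (kt + ko) * C[2:n]
    }
    dP <- ko * sum(C[2:n]) - pool_rate * P
    list(c(dC, dP))
  }
  sol <- deSolve::ode(y = initial_state, times = t_grid, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out) <- c("time", paste0("C", 1:n), "pool")
  per_min <- 1 / minutes_per_day()
  out$phagocytosis_flux <- kt * out[[paste0("C", n)]] * per_min
  out$pool_efflux_flux <- pool_rate * out$pool * per_min
  # external Ch requirement: disc formation minus the recycled share
  out$kin_ch <- params$j0_flux - f * out$pool_efflux_flux
  out
}

#' Mean disc residence time in the transit chain
#'
#' With no Ch efflux the steady-state chain holds `n * J0 / k_t` of material
#' per unit influx, i.e. discs spend on average `n / k_t` days in the ROS.
#'
#' @param params A [ros_chain_params()] object.
#' @return Mean residence time in days.
#' @export
mean_transit_time <- function(params) {
  stopifnot(inherits(params, "ros_chain_params"))
  params$n_compartments / params$k_t
}
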