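#' Named scenario tables reproducing the model's figures
#'
#' Each scenario recomputes one of the model's figure/table quantities as a
#' machine-readable data.frame:
#' \describe{
#'   \item{`fig5a`}{steady-state disc Ch profile and Ch/PL ratio along the
#'     transit chain}
#'   \item{`fig5b`}{Ch turnover rate versus the recycling fraction}
#'   \item{`fig6`}{RPE uptake curves versus choroidal LDL-Ch for backflux
#'     ratios 0.1, 0.5 and 1}
#'   \item{`fig7`}{linear drusen growth over 50 years at the bounding fluxes
#'     1 and 6 pg/mm^2/min}
#'   \item{`fig8a`}{drusen clearance versus macrophage density
#'     (0-5000 cells/mm^2)}
#'   \item{`fig8b`}{drusen clearance versus per-macrophage ABCA1 capacity
#'     (fold changes 0-10)}
#'   \item{`fig8c`}{drusen clearance versus BrM ApoA-I concentration
#'     (fold changes 0-10)}
#'   \item{`flux_table`}{the summary of all named fluxes, as
#'     [flux_summary()]}
#' }
#'
#' @param scenario_id One of the ids above.
#' @param params A `retchol_params` object, as from [load_parameters()].
#' @param overrides Named list of scenario-specific overrides. Supported:
#'   `h0` (um), `horizon_years`, `density_grid`, `vmax_folds`, `apoai_folds`,
#'   `f_grid`, `c_cc_max`, `grid_points`.
#' @return An object of class `scenario_result`: list with `scenario_id`,
#'   `tables` (named list of data.frames) and `metadata`.
#' @export
run_scenario <- function(scenario_id, params = load_parameters(),
                         overrides = list()) {
  stopifnot(inherits(params, "retchol_params"))
  valid <- c("fig5a", "fig5b", "fig6", "fig7", "fig8a", "fig8b", "fig8c",
             "flux_table")
  if (!scenario_id %in% valid) {
    stop("unknown scenario '", scenario_id, "'; valid ids: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  ov <- function(name, default) {
    if (name %in% names(overrides)) overrides[[name]] else default
  }

  tables <- switch(scenario_id,
    fig5a = {
      ss <- steady_state_profile(params$ros)
      list(profile = data.frame(
        compartment = seq_len(params$ros$n_compartments),
        ch_relative = ss$ch_per_compartment,
        ch_pl_ratio = ss$ch_pl_ratio_profile))
    },
    fig5b = {
      f <- ov("f_grid", seq(0, 1, by = 0.05))
      list(turnover = data.frame(
        f_recycling = f,
        kin_ch = turnover_rate(params$ros, f_recycling = f)))
    },
    fig6 = {
      grid <- seq(0, ov("c_cc_max", 100),
                  length.out = ov("grid_points", 101))
      list(uptake = uptake_curve(params$delivery, grid,
                                 pout_ratios = c(0.1, 0.5, 1)))
    },
    fig7 = {
      years <- seq(0, ov("horizon_years", 50), length.out = 101)
      rho <- params$efflux$deposit_ch_density
      list(growth = data.frame(
        years = years,
        height_low = drusen_height(drusen_growth_rate(1, rho), years),
        height_high = drusen_height(drusen_growth_rate(6, rho), years)))
    },
    fig8a = {
      dens <- ov("density_grid", c(0, 500, 1000, 2500, 5000))
      .clearance_family(dens, function(d) {
        m <- params$macrophage; m$density <- d; m
      }, "density", params, ov)
    },
    fig8b = {
      folds <- ov("vmax_folds", c(0, 0.25, 0.5, 1, 2, 5, 10))
      .clearance_family(folds, function(fd) {
        m <- params$macrophage; m$vmax_per_cell <- m$vmax_per_cell * fd; m
      }, "vmax_fold", params, ov)
    },
    fig8c = {
      folds <- ov("apoai_folds", c(0, 0.25, 0.5, 1, 2, 5, 10))
      .clearance_family(folds, function(fd) {
        m <- params$macrophage; m$c_apoai_brm <- m$c_apoai_brm * fd; m
      }, "apoai_fold", params, ov)
    },
    flux_table = list(fluxes = flux_summary(params))
  )

  structure(
    list(scenario_id = scenario_id,
         tables = tables,
         metadata = list(kout_mode = params$kout_mode,
                         overrides = overrides,
                         package_version =
                           as.character(utils::packageVersion("retchol")))),
    class = "scenario_result"
  )
}

# Family of clearance time courses, one level per value of a varied setting.
.clearance_family <- function(levels, modify, level_name, params, ov) {
  h0 <- ov("h0", 120)
  horizon <- ov("horizon_years", 10)
  rows <- lapply(levels, function(x) {
    tr <- drusen_clearance_timecourse(h0, modify(x), params$efflux,
                                      horizon_years = horizon)
    df <- data.frame(level = x,
                     years = tr$times / minutes_per_year(),
                     height = tr$heights)
    names(df)[1] <- level_name
    attr(df, "time_to_clear_years") <-
      tr$time_to_clear / minutes_per_year()
    df
  })
  clearance <- do.call(rbind, rows)
  summary <- data.frame(
    level = levels,
    time_to_clear_years =
      vapply(rows, function(d) attr(d, "time_to_clear_years"), numeric(1)))
  names(summary)[1] <- level_name
  list(clearance = clearance, time_to_clear = summary)
}

#' Summary of the model's named cholesterol fluxes
#'
#' One row per flux, all in pg/mm^2/min: the turnover rate at zero and full
#' recycling, the maximum LDLR uptake, apical and basal ABCA1 transport, and
#' ApoB-Ch particle secretion. All fall in the 1-13 pg/mm^2/min band.
#'
#' @param params A `retchol_params` object.
#' @return A data.frame with columns `flux`, `value`, `units`, `provenance`.
#' @export
flux_summary <- function(params = load_parameters()) {
  stopifnot(inherits(params, "retchol_params"))
  kout_basal <- basal_abca1_flux(params$efflux$kin_abca1,
                                 params$efflux$apical_basal_ratio)
  apob <- apob_ch_flux(params$efflux$hepatic_apob_flux,
                       params$efflux$apob_expr_frac,
                       params$efflux$mtp_expr_frac)
  data.frame(
    flux = c("Kin_Ch_f0", "Kin_Ch_f1", "Vmax_LDLR", "Kin_ABCA1",
             "Kout_ABCA1", "Kout_ApoB_Ch"),
    value = c(turnover_rate(params$ros, f_recycling = 0),
              turnover_rate(params$ros, f_recycling = 1),
              params$delivery$vmax_ldlr,
              abca1_apical_delivery(params$delivery),
              kout_basal,
              apob),
    units = "pg/mm2/min",
    provenance = c(
      "ROS turnover at zero recycling",
      "ROS turnover at complete recycling",
      "maximum LDLR-mediated uptake by the RPE",
      "apical ABCA1 transport to the outer retina",
      "basal ABCA1 efflux (apical flux / expression ratio)",
      "ApoB-Ch secretion (hepatic flux x expression fractions)"),
    stringsAsFactors = FALSE
  )
}

#' Monte-Carlo propagation of parameter uncertainties
#'
#' Draws `n` parameter sets with [sample_parameters()], recomputes the named
#' fluxes ([flux_summary()]) and the bounding drusen growth rates for each
#' draw, and summarises every output by its median and 2.5/97.5 percentiles.
#'
#' @param params A `retchol_params` object.
#' @param n Number of draws (>= 100).
#' @param seed Integer seed.
#' @param outputs Optional character vector restricting the summarised
#'   outputs.
#' @return A data.frame with columns `output`, `median`, `q2.5`, `q97.5`,
#'   `n`, `seed`.
#' @export
monte_carlo <- function(params = load_parameters(), n = 2000, seed = 1,
                        outputs = NULL) {
  stopifnot(inherits(params, "retchol_params"), n >= 100)
  draws <- sample_parameters(params, n, seed)
  per_draw <- vapply(draws, function(p) {
    fs <- flux_summary(p)
    vals <- c(fs$value,
              drusen_growth_rate(1, p$efflux$deposit_ch_density),
              drusen_growth_rate(
                apob_ch_flux(p$efflux$hepatic_apob_flux,
                             p$efflux$apob_expr_frac,
                             p$efflux$mtp_expr_frac),
                p$efflux$deposit_ch_density))
    names(vals) <- c(fs$flux, "drusen_growth_at_1", "drusen_growth_apob")
    vals
  }, numeric(8))
  if (!is.null(outputs)) {
    missing <- setdiff(outputs, rownames(per_draw))
    if (length(missing)) {
      stop("unknown output(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    per_draw <- per_draw[outputs, , drop = FALSE]
  }
  q <- apply(per_draw, 1, stats::quantile, probs = c(0.5, 0.025, 0.975))
  data.frame(output = colnames(q),
             median = q[1, ], q2.5 = q[2, ], q97.5 = q[3, ],
             n = n, seed = seed, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a scenario's tables as CSV files
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_scenario_csv <- function(result, out_dir = ".") {
  stopifnot(inherits(result, "scenario_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- vapply(names(result$tables), function(nm) {
    path <- file.path(out_dir,
                      paste0(result$scenario_id, "_", nm, ".csv"))
    utils::write.csv(result$tables[[nm]], path, row.names = FALSE)
    path
  }, character(1))
  invisible(unname(paths))
}
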