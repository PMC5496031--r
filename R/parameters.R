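#' Default parameter registry
#'
#' Every physical constant of the model lives in a flat registry: one row per
#' named quantity with its point value (in the unit it is usually quoted in),
#' its percent uncertainty (interpreted as the coefficient of variation of a
#' lognormal distribution; see [sample_parameters()]) and a provenance note.
#' Quantities whose uncertainty is not stated carry 0% and are held fixed
#' during Monte-Carlo sampling.
#'
#' @return A data.frame with columns `name`, `value`, `units`,
#'   `pct_uncertainty`, `source`.
#' @export
default_registry <- function() {
  row <- function(name, value, units, pct, source) {
    data.frame(name = name, value = value, units = units,
               pct_uncertainty = pct, source = source,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # --- rod outer segment transit chain ---
    row("Kin_discs", 85, "discs/day", 6,
        "rate of new disc formation entering the ROS"),
    row("k_t", 0.85, "1/day", 6,
        "first-order disc transfer rate within the ROS transit chain"),
    row("k_out", 0.19, "1/day", 34,
        "first-order Ch efflux rate from transit compartments 2-10"),
    row("Kin_Ch_f0", 5.84, "pg/mm2/min", 49,
        "Ch turnover flux anchor at zero recycling (f_recycling = 0)"),
    row("ch_pl_ratio_initial", 0.3, "mol/mol", 0,
        "Ch/PL molar ratio of newly formed discs"),
    row("fold_decrease", 6, "dimensionless", 0,
        "Ch content decrease from compartment 1 to 10"),
    row("n_compartments", 10, "count", 0,
        "number of transit-chain compartments"),
    row("discs_per_compartment", 100, "count", 0,
        "discs per transit-chain compartment"),
    # --- choroid-to-RPE delivery ---
    row("Pin_LDL", 1.2e-7, "cm/s", 7,
        "effective LDL transcytosis permeability, lumen to BrM"),
    row("Pout_ratio", 1, "dimensionless", 0,
        "Pout_LDL/Pin_LDL; assumed between 0.1 and 1"),
    row("Vmax_LDLR", 13.1, "pg/mm2/min", 50,
        "maximum LDLR-mediated LDL-Ch uptake flux by the RPE"),
    row("Km_LDLR", 5.4, "mg/dl", 9,
        "Michaelis constant of LDLR uptake, as LDL-Ch concentration"),
    row("Kin_ABCA1", 6.73, "pg/mm2/min", 50,
        "ABCA1-mediated Ch transport from apical RPE to the outer retina"),
    # --- basal efflux, drusen and macrophages ---
    row("apical_basal_ratio", 6.37, "dimensionless", 0,
        "apical:basal ABCA1 expression ratio in the RPE"),
    row("hepatic_ApoB_flux", 967, "pg/mm2/min", 50,
        "ApoB-Ch efflux rate if RPE secretion matched the hepatocyte"),
    row("ApoB_expr_frac", 0.075, "dimensionless", 0,
        "RPE ApoB mRNA expression relative to liver"),
    row("MTP_expr_frac", 0.04, "dimensionless", 0,
        "RPE MTP-A mRNA expression relative to liver"),
    row("P_ApoAI_Ch_CC", 1.2e-4, "cm/s", 41,
        "permeability of ApoA-I-Ch particles across the CC endothelium"),
    row("ch_to_apoai_mass_ratio", 0.14, "dimensionless", 0,
        "Ch:ApoA-I mass ratio of nascent ApoA-I-Ch particles (calibrated)"),
    row("reference_growth_flux", 1, "pg/mm2/min", 0,
        "ApoB-Ch flux at which the deposit density is calibrated"),
    row("reference_growth_rate", 0.7, "um/year", 0,
        "drusen growth rate at the reference flux (calibration point)"),
    row("Km_Mac", 5, "ug/ml", 35,
        "Michaelis constant of macrophage ABCA1 efflux, as ApoA-I conc."),
    row("vmax_Mac", 5.79e-2, "pg/cell/min", 27,
        "maximum ABCA1-mediated Ch efflux per macrophage"),
    row("C_ApoAI_BrM", 25, "ug/ml", 0,
        "baseline lipid-poor ApoA-I concentration in Bruch's membrane"),
    row("Mac_density", 1000, "cells/mm2", 0,
        "baseline macrophage density in Bruch's membrane")
  ))
}

.validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg),
            all(c("name", "value", "units", "pct_uncertainty", "source")
                %in% names(reg)))
  if (anyDuplicated(reg$name)) {
    stop("duplicate registry entries: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- reg$name[reg$value < 0]
  if (length(bad)) {
    stop("negative value for physical parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(reg$pct_uncertainty < 0)) {
    stop("percent_uncertainty must be >= 0", call. = FALSE)
  }
  invisible(reg)
}

#' Look up a registry value by name
#' @param params A `retchol_params` object or a registry data.frame.
#' @param name Parameter name (single string).
#' @return The point value (numeric scalar).
#' @export
registry_value <- function(params, name) {
  reg <- if (inherits(params, "retchol_params")) params$registry else params
  i <- match(name, reg$name)
  if (is.na(i)) stop("unknown parameter: '", name, "'", call. = FALSE)
  reg$value[i]
}

#' Assemble model parameters from a registry
#'
#' Builds the typed parameter groups (`ros`, `delivery`, `efflux`,
#' `macrophage`) used by the module functions from a flat registry. The
#' transit-chain Ch efflux constant `k_out` is taken either from the registry
#' entry (`kout_mode = "table"`, the printed rounded 0.19/day) or recalibrated
#' so that the chain reproduces the stated fold decrease in disc Ch exactly
#' (`kout_mode = "calibrated"`, the default; 0.1872/day for a 6-fold drop over
#' 9 steps).
#'
#' @param registry A registry data.frame, as from [default_registry()].
#' @param kout_mode `"calibrated"` or `"table"`.
#' @param f_recycling Fraction of disc-effluxed Ch recycled to the RIS.
#' @return An object of class `retchol_params`.
#' @export
build_model_parameters <- function(registry = default_registry(),
                                   kout_mode = c("calibrated", "table"),
                                   f_recycling = 0) {
  kout_mode <- match.arg(kout_mode)
  .validate_registry(registry)
  v <- function(name) registry_value(registry, name)

  ros <- ros_chain_params(
    n_compartments = v("n_compartments"),
    discs_per_compartment = v("discs_per_compartment"),
    disc_influx_rate = v("Kin_discs"),
    k_t = v("k_t"),
    k_out = if (kout_mode == "table") v("k_out") else
      calibrate_k_out(v("fold_decrease"), v("k_t"), v("n_compartments")),
    ch_pl_ratio_initial = v("ch_pl_ratio_initial"),
    j0_flux = v("Kin_Ch_f0"),
    f_recycling = f_recycling
  )
  delivery <- delivery_params(
    p_in_ldl = v("Pin_LDL"),
    pout_ratio = v("Pout_ratio"),
    vmax_ldlr = v("Vmax_LDLR"),
    km_ldlr = v("Km_LDLR"),
    kin_abca1 = v("Kin_ABCA1")
  )
  efflux <- efflux_params(
    kin_abca1 = v("Kin_ABCA1"),
    apical_basal_ratio = v("apical_basal_ratio"),
    hepatic_apob_flux = v("hepatic_ApoB_flux"),
    apob_expr_frac = v("ApoB_expr_frac"),
    mtp_expr_frac = v("MTP_expr_frac"),
    p_apoai_cc = v("P_ApoAI_Ch_CC"),
    ch_to_apoai_mass_ratio = v("ch_to_apoai_mass_ratio"),
    deposit_ch_density = deposit_density_from_growth_calibration(
      v("reference_growth_flux"), v("reference_growth_rate"))
  )
  macrophage <- macrophage_params(
    vmax_per_cell = v("vmax_Mac"),
    km_apoai = v("Km_Mac"),
    density = v("Mac_density"),
    c_apoai_brm = v("C_ApoAI_BrM")
  )

  structure(
    list(registry = registry, kout_mode = kout_mode,
         ros = ros, delivery = delivery, efflux = efflux,
         macrophage = macrophage),
    class = "retchol_params"
  )
}

#' Load model parameters, optionally overridden by a config file
#'
#' Without a config file this returns the default parameter set. A config is a
#' flat YAML mapping of registry names to numeric values; unknown keys are
#' rejected and negative values raise a validation error. A round trip through
#' [write_parameters()] and `load_parameters()` is lossless.
#'
#' @param config_path Path to a YAML config file, or `NULL` for defaults.
#' @param kout_mode,f_recycling Passed to [build_model_parameters()].
#' @return A `retchol_params` object.
#' @examples
#' p <- load_parameters()
#' registry_value(p, "k_t")  # 0.85
#' @export
load_parameters <- function(config_path = NULL,
                            kout_mode = c("calibrated", "table"),
                            f_recycling = 0) {
  kout_mode <- match.arg(kout_mode)
  reg <- default_registry()
  if (!is.null(config_path)) {
    cfg <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
      stop("malformed config file '", config_path, "': ",
           conditionMessage(e), call. = FALSE)
    })
    if (!is.null(cfg)) {
      unknown <- setdiff(names(cfg), reg$name)
      if (length(unknown)) {
        stop("unknown parameter key(s) in config: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      for (key in names(cfg)) {
        val <- cfg[[key]]
        if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
          stop("config key '", key, "' must be a single finite number",
               call. = FALSE)
        }
        if (val < 0) {
          stop("config key '", key, "' must be non-negative (got ", val, ")",
               call. = FALSE)
        }
        reg$value[reg$name == key] <- val
      }
    }
  }
  build_model_parameters(reg, kout_mode = kout_mode,
                         f_recycling = f_recycling)
}

#' Write the resolved registry values to a YAML config
#'
#' @param params A `retchol_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "retchol_params"))
  vals <- as.list(params$registry$value)
  names(vals) <- params$registry$name
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Export the resolved registry, with provenance, as JSON
#'
#' @param params A `retchol_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_registry_json <- function(params, path) {
  stopifnot(inherits(params, "retchol_params"))
  jsonlite::write_json(params$registry, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.retchol_params <- function(x, ...) {
  cat("<retchol_params> ", nrow(x$registry), " registry entries; k_out mode '",
      x$kout_mode, "' (k_out = ", signif(x$ros$k_out, 4), "/day); f_recycling = ",
      x$ros$f_recycling, "\n", sep = "")
  invisible(x)
}

#' Draw Monte-Carlo parameter sets from the registry uncertainties
#'
#' Each registry entry with a nonzero percent uncertainty is drawn from a
#' lognormal distribution whose median equals the point value and whose
#' coefficient of variation equals `pct_uncertainty / 100`; entries with zero
#' uncertainty are held fixed. Draws are independent across parameters and
#' replicates, and reproducible for a given seed.
#'
#' @param params A `retchol_params` object supplying the point values and the
#'   `kout_mode`/`f_recycling` configuration, which are preserved.
#' @param n Number of parameter sets to draw.
#' @param seed Integer seed.
#' @return A list of `n` `retchol_params` objects.
#' @export
sample_parameters <- function(params, n, seed) {
  stopifnot(inherits(params, "retchol_params"), n >= 1)
  reg <- params$registry
  cv <- reg$pct_uncertainty / 100
  sdlog <- sqrt(log1p(cv^2))   # lognormal: CV^2 = exp(sdlog^2) - 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  i_kt <- match("k_t", reg$name)
  i_discs <- match("Kin_discs", reg$name)
  lapply(seq_len(n), function(i) {
    draw <- reg
    factor <- exp(stats::rnorm(nrow(reg), 0, sdlog))  # median-preserving
    # k_t and Kin_discs are one measurement (k_t = Kin_discs per 100 discs):
    # perturb them jointly so the chain stays self-consistent
    if (!is.na(i_kt) && !is.na(i_discs)) factor[i_discs] <- factor[i_kt]
    draw$value <- reg$value * factor
    build_model_parameters(draw, kout_mode = params$kout_mode,
                           f_recycling = params$ros$f_recycling)
  })
}
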