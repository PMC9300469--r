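.config_defaults <- function() {
  list(
    landscape = list(n_minima = 2L, well_depth = 8, well_inverse_width = 20,
                     field_strength = 8, minima_offset_deg = 45),
    protocol = list(type = "square", duration_s = 40, period_s = 0.2,
                    amplitude_scale = 1, axis_deg = 0),
    simulation = list(damping = 0.1, thermal_energy = 1, dt = 2e-5,
                      record_stride = 200L, theta_init_deg = 45),
    rendering = list(rotor_radius_nm = 275, localization_sigma_nm = 20,
                     frame_rate_hz = 250),
    analysis = list(lags = c(2L, 4L, 6L), n_theta0 = 36L),
    mechanics = list(zeta_r = 4e-22, omega = 25, temp_K = 293, dg_atp_kT = 25),
    seed = 1L
  )
}

#' Validate a run configuration
#'
#' Reads a configuration from a YAML/JSON file or a nested list, fills in
#' defaults, and rejects unknown keys. The configuration mirrors the package
#' objects: `landscape` ([rotor_landscape()] fields with the offset in
#' degrees), `protocol` (single-segment drive: type `square`/`dc`/`off`,
#' duration, period, amplitude scale, axis in degrees), `simulation`
#' ([sim_config()] fields with the initial angle in degrees), `rendering`
#' ([render_tip_positions()] fields), `analysis` (entropy-production lags),
#' `mechanics` calculator inputs, and the global `seed`.
#'
#' @param config a nested list, or a path to a YAML or JSON file.
#' @return the completed configuration list (class `run_config`), or an error
#'   listing every offending key.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- .config_defaults()
  errors <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top)) {
    errors <- c(errors, paste0("unknown section(s): ", paste(unknown_top, collapse = ", ")))
  }
  for (sec in intersect(names(config), names(defaults))) {
    if (sec == "seed") next
    unknown <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(unknown)) {
      errors <- c(errors, paste0("unknown key(s) in ", sec, ": ",
                                 paste(unknown, collapse = ", ")))
    }
  }
  merged <- modifyList(defaults, config)
  if (merged$landscape$well_depth < 0) errors <- c(errors, "landscape.well_depth must be >= 0")
  if (merged$landscape$well_inverse_width <= 0) errors <- c(errors, "landscape.well_inverse_width must be > 0")
  if (merged$landscape$field_strength < 0) errors <- c(errors, "landscape.field_strength must be >= 0")
  if (merged$landscape$n_minima < 1) errors <- c(errors, "landscape.n_minima must be >= 1")
  if (!merged$protocol$type %in% c("square", "dc", "off")) {
    errors <- c(errors, "protocol.type must be one of square, dc, off")
  }
  if (merged$protocol$duration_s <= 0) errors <- c(errors, "protocol.duration_s must be > 0")
  if (merged$simulation$dt <= 0) errors <- c(errors, "simulation.dt must be > 0")
  if (length(errors)) stop(paste(errors, collapse = "\n"))
  ls <- rotor_landscape(merged$landscape$n_minima, merged$landscape$well_depth,
                        merged$landscape$well_inverse_width,
                        merged$landscape$field_strength,
                        deg2rad(merged$landscape$minima_offset_deg))
  pr <- field_protocol(data.frame(
    duration = merged$protocol$duration_s, waveform = merged$protocol$type,
    period = merged$protocol$period_s,
    amplitude_scale = merged$protocol$amplitude_scale,
    axis_angle = deg2rad(merged$protocol$axis_deg)
  ))
  cfg <- sim_config(merged$simulation$damping, merged$simulation$thermal_energy,
                    merged$simulation$dt, merged$simulation$record_stride,
                    seed = merged$seed,
                    theta_init = deg2rad(merged$simulation$theta_init_deg))
  .stability_check(ls, pr, cfg)
  merged$objects <- list(landscape = ls, protocol = pr, sim = cfg)
  class(merged) <- "run_config"
  merged
}

# per-stage seeds derived from the global seed so stages can be re-run in
# isolation: simulation uses seed, rendering uses seed + 10^6 (kept < 2^31)
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, render = 1000000L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> render -> track -> irreversibility -> mechanics for
#' one configured motor and writes all artifacts into `out_dir`: the
#' trajectory CSV (`time_s, theta_unwrapped_deg`), the tracked tip-position
#' CSV with its metadata sidecar, a JSON report (per-run speeds, entropy
#' production, effective coefficients, mechanics), the echoed configuration
#' and a plain-text summary.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @param out_dir output directory, created if needed.
#' @return the report list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  ob <- config$objects
  ob$sim$seed <- .stage_seed(config$seed, "simulate")
  traj <- stage("simulate", simulate_motor(ob$landscape, ob$protocol, ob$sim))
  traj_df <- data.frame(time_s = traj$times,
                        theta_unwrapped_deg = rad2deg(traj$theta))
  write.csv(traj_df, file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  tips <- stage("render", render_tip_positions(
    traj, config$rendering$rotor_radius_nm,
    config$rendering$localization_sigma_nm, config$rendering$frame_rate_hz,
    seed = .stage_seed(config$seed, "render")
  ))
  write_positions(tips, file.path(out_dir, "tips.csv"))
  track <- stage("track", {
    wrapped <- angles_from_positions(tips)
    unwrapped <- unwrap_angles(wrapped)
    list(omega_deg_s = angular_velocity(tips),
         net_turns = (unwrapped[length(unwrapped)] - unwrapped[1]) / (2 * pi))
  })
  thermo <- if (config$protocol$type == "square" &&
                config$protocol$duration_s >= 100 * config$protocol$period_s) {
    stage("thermo", {
      ec <- entropy_production(traj, config$protocol$period_s,
                               lags = config$analysis$lags,
                               n_theta0 = config$analysis$n_theta0)
      list(slope_per_deg = ec$slope, per_lag_slopes = unname(ec$slopes),
           omega_eff_deg_s = ec$omega_eff, D_eff_deg2_s = ec$D_eff)
    })
  } else NULL
  mech <- stage("mechanics", {
    m <- mechanics_report(config$mechanics$omega, zeta_r = config$mechanics$zeta_r,
                          temp_K = config$mechanics$temp_K,
                          dg_atp_kT = config$mechanics$dg_atp_kT)
    m[c("torque_pN_nm", "power_pN_nm_s", "power_kT_s", "atp_per_s")]
  })
  report <- list(
    package_version = as.character(utils::packageVersion("rotaratchet")),
    seed = config$seed,
    tracking = track, thermo = thermo, mechanics = mech,
    drift_nonzero = abs(track$omega_deg_s) > 0
  )
  cfg_echo <- config[setdiff(names(config), "objects")]
  jsonlite::write_json(cfg_echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("rotaratchet pipeline, seed %d", config$seed),
    sprintf("net speed: %.2f deg/s (%.2f turns total)",
            track$omega_deg_s, track$net_turns),
    if (!is.null(thermo)) sprintf("entropy-production slope: %.4g per deg (omega_eff %.2f deg/s, D_eff %.2f deg^2/s)",
                                  thermo$slope_per_deg, thermo$omega_eff_deg_s,
                                  thermo$D_eff_deg2_s),
    sprintf("mechanics: %.3g pN nm, %.3g pN nm/s, %.3g kT/s, %.3g ATP/s",
            mech$torque_pN_nm, mech$power_pN_nm_s, mech$power_kT_s, mech$atp_per_s)
  ), file.path(out_dir, "summary.txt"))
  invisible(report)
}
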