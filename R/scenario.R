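## Scenario runner: configuration, presets, and end-to-end runs.

default_config <- function() {
  list(
    tissue = list(density = 1000, specific_heat = 4187, conductivity = 0.628,
                  youngs_modulus = 100e6, poisson = 0.4,
                  thermal_expansion = 1e-4, damping = 0, relaxation_time = 3,
                  reference_temperature_C = 37),
    blood = list(density = 1060, specific_heat = 3860,
                 perfusion_rate = 1.87e-3, artery_temperature_C = NULL),
    optics = list(intensity = 3e5, absorption = 18, scattering = 8000,
                  anisotropy = 0.9, diffuse_reflectance = 0.05,
                  O1 = NULL, O2 = NULL, e1 = NULL, e2 = NULL),
    profile = list(family = "step", time_units = "nondim", step_time = 0.2,
                   onset = 0, period = 0.1, width = 0.05, n_stairs = 3,
                   dwell = 0.05, repeat_time = 0.1, omega_r = 2 * pi,
                   epsilon = NULL, t_max = 2),
    solver = list(t_end = 0.5, rtol = 1e-6, atol = 1e-9, max_step = NULL,
                  n_out = 2001),
    quadrature = list(rmax = 12, zmax = 12, tol = 1e-9),
    oracle_grid = list(rmax = 12, zmax = 12, nr = 121, nz = 121, dt = NULL),
    output = list(probe_r = 0, probe_z = 0, snapshot_times = numeric(0),
                  grid_r = seq(0, 4, by = 0.25), grid_z = seq(0, 4, by = 0.25)),
    flags = list(coupling = TRUE, oracle = FALSE),
    seed = 1L
  )
}

#' Build a scenario configuration
#'
#' Starts from the bundled skin/blood/laser parameter defaults and merges the
#' supplied blocks over them; every key is validated and all offending keys
#' are reported together.  `profile$time_units` may be `"nondim"` (times in
#' units of t*) or `"seconds"` (times converted using the derived t*;
#' `solver$t_end` follows the same units).
#'
#' @param ... named blocks (`tissue`, `blood`, `optics`, `profile`, `solver`,
#'   `quadrature`, `oracle_grid`, `output`, `flags`, `seed`) with partial
#'   overrides
#' @return validated configuration list of class `scenario_config`
#' @export
scenario_config <- function(...) {
  over <- list(...)
  merge_validate(default_config(), over)
}

merge_validate <- function(base, over) {
  bad <- character(0)
  for (blk in names(over)) {
    if (!blk %in% names(base)) { bad <- c(bad, blk); next }
    if (!is.list(base[[blk]])) { base[[blk]] <- over[[blk]]; next }
    if (!is.list(over[[blk]])) { bad <- c(bad, blk); next }
    unknown <- setdiff(names(over[[blk]]), names(base[[blk]]))
    if (length(unknown)) bad <- c(bad, paste0(blk, "$", unknown))
    for (k in intersect(names(over[[blk]]), names(base[[blk]]))) {
      base[[blk]][k] <- list(over[[blk]][[k]])
    }
  }
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (!base$profile$time_units %in% c("nondim", "seconds")) {
    stop("profile$time_units must be 'nondim' or 'seconds'")
  }
  structure(base, class = c("scenario_config", "list"))
}

#' Read a scenario configuration from a YAML file
#'
#' @param path YAML file with any subset of the configuration blocks
#' @return validated configuration
#' @export
read_scenario_config <- function(path) {
  merge_validate(default_config(), yaml::read_yaml(path))
}

#' Named scenario presets
#'
#' Presets mirror the studied heating scenarios: `fig3_single_pulse`,
#' `fig6_repetitive`, `fig8a_stairs` (stairs in cooling), `fig8b_stairs`
#' (stairs in heating), `fig8c_stairs` (symmetric), `fig9_step`, `fig11_ramp`,
#' `fig12_harmonic`, the validation cases `table2_5s`, `table2_8s`,
#' `table2_10s`, `table2_15s` (single 122 kW/m2 pulse of the stated exposure,
#' thermoelastic coupling off), and `null_source` (zero intensity).
#'
#' @param name preset name
#' @return a [scenario_config()]
#' @export
preset_config <- function(name) {
  table2 <- function(exposure_s) scenario_config(
    optics = list(intensity = 122e3),
    profile = list(family = "single_pulse", time_units = "seconds",
                   step_time = exposure_s, t_max = 3 * exposure_s),
    solver = list(t_end = 1.6 * exposure_s),
    flags = list(coupling = FALSE)
  )
  switch(name,
    fig3_single_pulse = scenario_config(
      profile = list(family = "single_pulse", step_time = 0.2),
      solver = list(t_end = 0.5)),
    fig6_repetitive = scenario_config(
      profile = list(family = "repetitive_pulse", period = 0.1, width = 0.05),
      solver = list(t_end = 0.8)),
    fig8a_stairs = scenario_config(
      profile = list(family = "stairs_cooling", n_stairs = 3, dwell = 0.05),
      solver = list(t_end = 0.4)),
    fig8b_stairs = scenario_config(
      profile = list(family = "stairs_heating", n_stairs = 3, dwell = 0.05),
      solver = list(t_end = 0.4)),
    fig8c_stairs = scenario_config(
      profile = list(family = "stairs_symmetric", n_stairs = 3, dwell = 0.05),
      solver = list(t_end = 0.4)),
    fig9_step = scenario_config(
      profile = list(family = "step"), solver = list(t_end = 0.6)),
    fig11_ramp = scenario_config(
      profile = list(family = "repetitive_ramp", repeat_time = 0.1),
      solver = list(t_end = 0.8)),
    fig12_harmonic = scenario_config(
      profile = list(family = "harmonic", omega_r = 2 * pi),
      solver = list(t_end = 1)),
    table2_5s = table2(5), table2_8s = table2(8),
    table2_10s = table2(10), table2_15s = table2(15),
    null_source = scenario_config(
      optics = list(intensity = 0),
      profile = list(family = "step"), solver = list(t_end = 0.3)),
    stop("unknown preset: ", name)
  )
}

# Build model objects from a configuration; converts second-based profile
# times to nondimensional units using the derived t*.
config_objects <- function(config) {
  tissue <- do.call(tissue_model, config$tissue)
  blood <- do.call(blood_model, config$blood)
  optics <- do.call(laser_optics, config$optics)
  groups <- nondim_groups(tissue, blood, optics)
  pr <- config$profile
  t_end <- config$solver$t_end
  if (pr$time_units == "seconds") {
    ts <- groups$tstar
    for (k in c("step_time", "onset", "period", "width", "dwell",
                "repeat_time", "t_max")) pr[[k]] <- pr[[k]] / ts
    if (!is.null(pr$epsilon)) pr$epsilon <- pr$epsilon / ts
    t_end <- t_end / ts
  }
  pr$time_units <- NULL
  profile <- do.call(time_profile, pr)
  settings <- rom_settings(config$quadrature$rmax, config$quadrature$zmax,
                           config$quadrature$tol)
  list(tissue = tissue, blood = blood, optics = optics, groups = groups,
       profile = profile, settings = settings, t_end = t_end)
}

#' Run a scenario end to end
#'
#' Assembles the reduced system, integrates it, reconstructs any requested
#' snapshots, writes all outputs as delimited text into `out_dir` (trajectory,
#' snapshots, metrics report, run log with every derived constant, and a
#' verbatim echo of the configuration), and optionally runs the
#' finite-difference oracle on the same source.
#'
#' @param config a [scenario_config()] or preset name
#' @param out_dir output directory (created if missing); `NULL` skips writing
#' @return invisibly, a list with `trajectory`, `metrics`, `system`,
#'   `snapshots`, `oracle` and `paths`
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- preset_config(config)
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)  # reserved; the core pipeline is deterministic
  ob <- config_objects(config)
  system <- assemble_reduced_system(ob$groups, ob$optics, ob$profile,
                                    coupling = isTRUE(config$flags$coupling),
                                    settings = ob$settings)
  traj <- integrate_system(system, ob$t_end, rtol = config$solver$rtol,
                           atol = config$solver$atol,
                           max_step = config$solver$max_step,
                           n_out = config$solver$n_out)
  metrics <- summarize_run(traj, config$output$probe_r, config$output$probe_z)
  snaps <- lapply(config$output$snapshot_times, function(tt) {
    reconstruct_fields(traj, config$output$grid_r, config$output$grid_z, tt)
  })
  oracle <- NULL
  if (isTRUE(config$flags$oracle)) {
    og <- config$oracle_grid
    oracle <- fd_solve(fd_grid(og$rmax, og$zmax, og$nr, og$nz, og$dt),
                       ob$groups, ob$optics, ob$profile, ob$t_end)
  }
  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_run(out_dir, config, ob, system, traj, metrics, snaps, oracle)
  }
  invisible(list(trajectory = traj, metrics = metrics, system = system,
                 snapshots = snaps, oracle = oracle, config = config,
                 paths = paths))
}

write_run <- function(out_dir, config, ob, system, traj, metrics, snaps, oracle) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cfg <- config
  cfg$blood$artery_temperature_C <- cfg$blood$artery_temperature_C %||% "body"
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  tr <- as.data.frame(traj)
  tr[] <- lapply(tr, function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(tr, p("trajectory.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- system$groups
  log_lines <- c(
    "# derived constants",
    sprintf("lambda_Pa: %.10g", g$lambda),
    sprintf("mu_Pa: %.10g", g$mu),
    sprintf("thermal_modulus_Pa_per_K: %.10g", g$thermal_modulus),
    sprintf("alpha_m2_s: %.10g", g$alpha),
    sprintf("delta_m: %.10g", g$delta),
    sprintf("tstar_s: %.10g", g$tstar),
    sprintf("theta_b: %.10g", g$theta_b),
    vapply(c(paste0("M", 1:7), paste0("N", 1:7)),
           function(k) sprintf("%s: %.10g", k, g[[k]]), ""),
    sprintf("d1: %.10g", system$bc$d1),
    sprintf("d2: %.10g", system$bc$d2),
    sprintf("d3: %.10g", system$bc$d3))
  writeLines(log_lines, p("log.txt"))
  writeLines(c(
    sprintf("max_T_C: %.6f", metrics$max_T_C),
    sprintf("peak_time_nondim: %.6f", metrics$peak_time),
    sprintf("peak_time_seconds: %.6f", metrics$peak_time_seconds),
    sprintf("overshoot_theta: %.6g", metrics$overshoot),
    sprintf("osc_amplitude_theta: %.6g", metrics$osc_amplitude)),
    p("metrics.txt"))
  for (i in seq_along(snaps)) {
    utils::write.table(snaps[[i]], p(sprintf("snapshot_%03d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(oracle)) {
    utils::write.table(
      data.frame(t = oracle$times, theta_surface = oracle$surface_theta),
      p("oracle_surface.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(dir = out_dir, trajectory = p("trajectory.tsv"),
       metrics = p("metrics.txt"), log = p("log.txt"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
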