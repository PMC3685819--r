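# Reporting layer: a run configuration, the five analysis commands that
# regenerate the study's tables and figure datasets, and plain-text export
# with embedded provenance (config hash, scale mode, calibration).

#' Build or load a run configuration
#'
#' `default_run_config()` returns the configuration describing the default
#' study conditions; `read_run_config()` loads a YAML file whose top-level
#' keys override those defaults. Fields: `solute_registry` (optional path),
#' `interface` (list of [interface_spec()] arguments), `scenario` (list of
#' `potentials`/`flux_targets`), `scale_mode`, `calibration`, `out_dir`
#' (optional), `seed`.
#'
#' @param ... Named overrides of the default fields.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    solute_registry = NULL,
    interface = list(pd_density = 14, neck_length = 0.18,
                     wall_thickness = 0.1, measured_deff = 0.41),
    scenario = list(potentials = c(sucrose = 60, raffinose = 67,
                                   stachyose = 334),
                    flux_targets = c(cucumis_melo = 9.7e-7)),
    geometry = list(channel = list(pore_radius = 6.4, channels_per_pd = 9),
                    slit = list(half_width = 5.2),
                    hydrogel = list(volume_fraction = 0.49, fiber_radius = 15)),
    scale_mode = "literal",
    calibration = 1,
    out_dir = NULL,
    seed = 1L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (cfg$calibration <= 0) stop_invalid("calibration", "must be > 0")
  class(cfg) <- "run_config"
  cfg
}

#' @param path Path to a YAML configuration file.
#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_run_config, raw)
}

config_solutes <- function(config) {
  if (!is.null(config$solute_registry)) read_solute_registry(config$solute_registry)
  else default_solutes()
}

config_interface <- function(config) do.call(interface_spec, config$interface)

# write a data.frame as TSV with a commented provenance header
write_report <- function(df, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, paste0(name, ".tsv"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", config_hash(unclass(config))), con)
  writeLines(sprintf("# scale_mode: %s", config$scale_mode), con)
  writeLines(sprintf("# calibration: %g", config$calibration), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", row.names = FALSE,
                                      quote = FALSE))
  invisible(path)
}

#' Solute radius table
#'
#' Side-by-side hydrodynamic radii: the registry value, the Stokes-Einstein
#' radius implied by the bulk diffusivity, and the radii recovered by
#' inverting the 1000-fold channel and slit hindrance cut-offs evaluated at
#' the registry radius.
#'
#' @param config A `run_config`.
#' @return A data.frame, one row per solute.
#' @export
cmd_radii <- function(config = default_run_config()) {
  solutes <- config_solutes(config)
  rows <- lapply(solutes, function(s) {
    chan_cut <- invert_geometry("channel", s$r_hyd, 1e-3)
    slit_cut <- invert_geometry("slit", s$r_hyd, 1e-3)
    data.frame(
      name = s$name,
      d_water_m2_per_s = s$d_water,
      r_hyd_registry_angstrom = s$r_hyd,
      r_hyd_stokes_einstein_angstrom = stokes_einstein_radius(s$d_water),
      r_from_channel_cutoff_angstrom =
        recover_radius_from_cutoff("channel", chan_cut, 1000),
      r_from_slit_cutoff_angstrom =
        recover_radius_from_cutoff("slit", slit_cut, 1000),
      cutoff_channel_angstrom = chan_cut,
      cutoff_slit_angstrom = slit_cut)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_report(out, config, "radii")
  out
}

#' Hindrance-curve dataset for all three substructure models
#'
#' @param config A `run_config`.
#' @param dimensions Grid of channel radii / slit half-widths, angstrom.
#' @param volume_fractions Grid of hydrogel polymer volume fractions.
#' @return A data.frame (`model`, `dimension_angstrom`, `solute`, `lambda`,
#'   `hindrance`).
#' @export
cmd_hindrance <- function(config = default_run_config(),
                          dimensions = seq(4, 40, by = 0.5),
                          volume_fractions = seq(0, 0.6, by = 0.05)) {
  solutes <- config_solutes(config)
  cs <- hindrance_curve(solutes, dimensions, models = c("channel", "slit"))
  hg <- hindrance_curve(solutes, volume_fractions, models = "hydrogel",
                        fiber_radius = config$geometry$hydrogel$fiber_radius)
  out <- rbind(cs, hg)
  write_report(out, config, "hindrance")
  out
}

#' Matching curve and cross-configuration consistency
#'
#' Finds, for each candidate channel count, the channel radius at which
#' the predicted wall-level effective diffusion coefficient matches the
#' measured one, and reports the per-PD conductance consistency of the
#' configured channel/slit/hydrogel geometries for the tracer solute.
#'
#' @param config A `run_config`.
#' @param channel_counts Channel-count candidates.
#' @param tracer Name of the tracer solute in the registry.
#' @return A list with `matching` (data.frame) and `consistency` (list).
#' @export
cmd_match <- function(config = default_run_config(), channel_counts = 1:20,
                      tracer = "fluorescein") {
  solutes <- config_solutes(config)
  interface <- config_interface(config)
  s <- solutes[[tracer]]
  if (is.null(s)) stop_invalid("tracer", "not found in solute registry")
  mc <- matching_curve(interface, interface$measured_deff, s,
                       channel_counts = channel_counts,
                       scale_mode = config$scale_mode,
                       calibration = config$calibration)
  g <- config$geometry
  configs <- list(
    do.call(channel_geometry, g$channel),
    do.call(slit_geometry, g$slit),
    do.call(hydrogel_geometry, g$hydrogel))
  cons <- cross_configuration_consistency(configs, interface, s)
  write_report(mc, config, "matching_curve")
  write_report(cons$table, config, "consistency")
  list(matching = mc, consistency = cons)
}

#' Flux profiles, required potentials and the leaf-export comparison
#'
#' Regenerates the flux-versus-potential dataset for the configured
#' channel geometry, the required concentration potentials for each
#' configured flux target, and the leaf-export conversion, in strict SI
#' and (when `calibration != 1`) calibrated form.
#'
#' @param config A `run_config`.
#' @param export_spec A [leaf_export_spec()].
#' @return A list with `profile`, `required_potentials_mM`, `leaf_export`.
#' @export
cmd_flux <- function(config = default_run_config(),
                     export_spec = leaf_export_spec()) {
  solutes <- config_solutes(config)
  interface <- config_interface(config)
  scen <- do.call(transport_scenario, config$scenario)
  geom <- do.call(channel_geometry, config$geometry$channel)
  sugars <- solutes[intersect(names(solutes), names(scen$potentials))]
  prof <- flux_potential_profile(geom, interface, sugars,
                                 scenario = scen,
                                 calibration = config$calibration)
  req <- vapply(names(scen$flux_targets), function(tg) {
    required_potential(scen$flux_targets[[tg]], geom, interface,
                       solutes$sucrose, calibration = config$calibration)
  }, numeric(1))
  export <- leaf_export_to_interface_flux(export_spec)
  write_report(prof, config, "flux_profile")
  write_report(data.frame(target = names(req), required_potential_mM = req),
               config, "required_potentials")
  list(profile = prof, required_potentials_mM = req, leaf_export = export)
}

#' Synthetic tracer experiment and sensitivity summary
#'
#' Simulates a two-compartment equilibration at the configured measured
#' effective diffusion coefficient, recovers it (noise-free and at the
#' given noise level), and propagates lognormal radius uncertainty into
#' the channel hindrance of the configured channel geometry.
#'
#' @param config A `run_config`.
#' @param noise_sd Relative noise level for the noisy recovery.
#' @param n_replicates Noisy replicates for the recovery summary.
#' @param n_scenarios Lognormal draws for the sensitivity summary.
#' @param radius_cv Coefficient of variation on the solute radii.
#' @return A list with `recovery` (data.frame) and `sensitivity`
#'   (quantile summary of channel hindrance per solute).
#' @export
cmd_simulate <- function(config = default_run_config(), noise_sd = 0.02,
                         n_replicates = 50, n_scenarios = 200,
                         radius_cv = 0.02) {
  interface <- config_interface(config)
  truth <- interface$measured_deff
  # window of ~3 decay times at the target D_eff: tau = d/(P A (1/Va+1/Vb))
  tau <- interface$neck_length * 500 / (truth * 50)
  geom_args <- list(volume_a = 1000, volume_b = 1000, contact_area = 50,
                    wall_thickness = interface$neck_length,
                    duration = 3 * tau, dt = 3 * tau / 60)
  tr0 <- do.call(simulate_equilibration,
                 c(list(d_eff = truth, seed = config$seed), geom_args))
  est0 <- estimate_deff(tr0)$d_eff
  ests <- vapply(seq_len(n_replicates), function(i) {
    tr <- do.call(simulate_equilibration,
                  c(list(d_eff = truth, noise_sd = noise_sd,
                         seed = config$seed + i), geom_args))
    estimate_deff(tr)$d_eff
  }, numeric(1))
  recovery <- data.frame(
    truth_um2_s = truth, noise_free_estimate = est0,
    noisy_median = stats::median(ests), noisy_sd = stats::sd(ests),
    n_replicates = n_replicates, noise_sd = noise_sd)

  solutes <- config_solutes(config)
  sugars <- solutes[setdiff(names(solutes), "fluorescein")]
  params <- data.frame(name = names(sugars),
                       base = vapply(sugars, `[[`, numeric(1), "r_hyd"),
                       cv = radius_cv)
  draws <- generate_scenarios(params, n_scenarios, seed = config$seed)
  rp <- config$geometry$channel$pore_radius
  sens <- do.call(rbind, lapply(names(sugars), function(nm) {
    h <- hindrance_channel(pmin(draws[[nm]] / rp, 2))
    q <- stats::quantile(h, c(0.05, 0.5, 0.95))
    data.frame(solute = nm, pore_radius_angstrom = rp,
               h_q05 = q[[1]], h_q50 = q[[2]], h_q95 = q[[3]])
  }))
  write_report(recovery, config, "recovery")
  write_report(sens, config, "sensitivity")
  list(recovery = recovery, sensitivity = sens)
}
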