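# Hindered Fick flux across the BSC-IC interface and its inversion to
# required concentration potentials, plus the leaf-export conversion.
# Direction convention: positive flux is BSC -> IC; RFO "leakage" is the
# positive flux of raffinose/stachyose obtained by applying the potential
# with reversed sign (IC -> BSC).

#' Transport scenario: concentration potentials and flux constraints
#'
#' @param potentials Named numeric vector of per-solute concentration
#'   potentials across the BSC-IC interface, mM. Defaults: sucrose 60,
#'   raffinose 67, stachyose 334.
#' @param flux_targets Named numeric vector of literature flux values to
#'   compare against, mol m^-2 s^-1.
#' @return An object of class `transport_scenario`.
#' @export
transport_scenario <- function(potentials = c(sucrose = 60, raffinose = 67,
                                              stachyose = 334),
                               flux_targets = c(cucumis_melo = 9.7e-7)) {
  check_nonnegative(potentials, "potentials")
  if (length(flux_targets) && any(flux_targets <= 0))
    stop_invalid("flux_targets", "must be strictly positive")
  structure(list(potentials = potentials, flux_targets = flux_targets),
            class = "transport_scenario")
}

#' Leaf carbon-export specification
#'
#' Parameters of the conversion from a leaf-level carbon export rate to a
#' molar flux density across the BSC-IC interface.
#'
#' @param export_rate Leaf export rate, mg CH2O per dm^2 leaf per hour
#'   (default 4.25).
#' @param interface_area_per_leaf_area BSC-IC interface area per leaf area,
#'   mm^2 per dm^2 (default 3558).
#' @param molar_mass_ch2o g mol^-1 (default 30.026).
#' @param molar_mass_sucrose g mol^-1 (default 342.30).
#' @return An object of class `leaf_export_spec`.
#' @export
leaf_export_spec <- function(export_rate = 4.25,
                             interface_area_per_leaf_area = 3558,
                             molar_mass_ch2o = 30.026,
                             molar_mass_sucrose = 342.30) {
  check_nonnegative(export_rate, "export_rate")
  check_positive(interface_area_per_leaf_area, "interface_area_per_leaf_area")
  check_positive(molar_mass_ch2o, "molar_mass_ch2o")
  check_positive(molar_mass_sucrose, "molar_mass_sucrose")
  structure(list(export_rate = export_rate,
                 interface_area_per_leaf_area = interface_area_per_leaf_area,
                 molar_mass_ch2o = molar_mass_ch2o,
                 molar_mass_sucrose = molar_mass_sucrose),
            class = "leaf_export_spec")
}

#' Hindered Fick flux density within a pore
#'
#' \eqn{J = H D \Delta c / d}: flux per unit pore cross-section for a
#' solute with hindrance factor H, diffusivity D, concentration potential
#' delta-c across a diffusion distance d.
#'
#' @param hindrance Hindrance factor H in \[0, 1\].
#' @param d_coef Diffusivity (bulk or cytosolic), m^2 s^-1.
#' @param delta_c Concentration potential, mol m^-3 (numerically equal to mM).
#' @param d Diffusion distance, um.
#' @return Flux density in mol um^-2 s^-1.
#' @examples
#' pore_flux_density(1, 5e-10, 60, 0.18)  # 1.67e-13
#' @export
pore_flux_density <- function(hindrance, d_coef, delta_c, d) {
  if (!is.numeric(hindrance) || any(hindrance < 0) || any(hindrance > 1))
    stop_invalid("hindrance", "must lie in [0, 1]")
  check_positive(d_coef, "d_coef")
  check_nonnegative(delta_c, "delta_c")
  check_positive(d, "d")
  d_um2 <- d_coef * M2S_TO_UM2S       # um^2 s^-1
  c_um3 <- delta_c * 1e-18            # mol m^-3 -> mol um^-3
  hindrance * d_um2 * c_um3 / d
}

#' Wall-level interface flux of a solute through one substructure
#'
#' Chains the per-pore hindered Fick flux with the open-area fraction of
#' the wall (PD density times per-PD open cross-section) to give the flux
#' density per unit wall area. The slit and hydrogel geometries need their
#' absolute cross-section parameters (`slit_circumference`,
#' `cross_section_radius`) for this; without them only per-pore and
#' relative quantities are defined.
#'
#' @param geometry A `pd_geometry`.
#' @param interface An [interface_spec()] (supplies PD density and neck
#'   length).
#' @param solute A [solute_spec()]; its cytosolic diffusivity is used.
#' @param delta_c Concentration potential, mM (mol m^-3). May be negative
#'   to express reversed (IC -> BSC) driving.
#' @param calibration Positive scalar multiplying the wall-level flux
#'   (default 1); see [effective_diffusion()].
#' @return A list of class `flux_result`: `pore_flux_density`
#'   (mol um^-2 s^-1), `area_fraction` (dimensionless), `interface_flux`
#'   (mol m^-2 s^-1), `calibration`.
#' @examples
#' interface_flux(channel_geometry(6.4, 9), interface_spec(),
#'                default_solutes()$sucrose, delta_c = 60)
#' @export
interface_flux <- function(geometry, interface, solute, delta_c,
                           calibration = 1) {
  stopifnot(inherits(interface, "interface_spec"))
  check_positive(calibration, "calibration")
  if (!is.numeric(delta_c) || length(delta_c) != 1L || is.na(delta_c))
    stop_invalid("delta_c", "must be a single number (mM)")
  hf <- hindrance_factor(geometry, solute)
  sgn <- if (delta_c < 0) -1 else 1
  j_pore <- sgn * pore_flux_density(hf$hindrance, d_cytosol(solute),
                                    abs(delta_c), interface$neck_length)
  area <- pd_open_area_um2(geometry)
  if (is.na(area))
    stop(paste("missing parameter: absolute interface flux needs",
               "slit_circumference (slit) or cross_section_radius (hydrogel)"),
         call. = FALSE)
  area_fraction <- interface$pd_density * area
  # mol um^-2 s^-1 -> mol m^-2 s^-1
  j_wall <- j_pore * area_fraction * 1e12 * calibration
  structure(list(pore_flux_density = j_pore, area_fraction = area_fraction,
                 interface_flux = j_wall, hindrance = hf$hindrance,
                 calibration = calibration),
            class = "flux_result")
}

#' Concentration potential required for a target interface flux
#'
#' Inverts [interface_flux()] in the concentration potential: because the
#' flux is strictly linear in delta-c, the answer is the target flux
#' divided by the wall-level conductance (flux at 1 mM).
#'
#' @param j_target Target wall-level flux, mol m^-2 s^-1 (> 0).
#' @inheritParams interface_flux
#' @return Required potential in mM.
#' @export
required_potential <- function(j_target, geometry, interface, solute,
                               calibration = 1) {
  check_nonnegative(j_target, "j_target")
  if (j_target == 0) return(0)
  hf <- hindrance_factor(geometry, solute)
  if (hf$hindrance == 0)
    stop("infeasible: hindrance is 0, no potential achieves this flux",
         call. = FALSE)
  conductance <- interface_flux(geometry, interface, solute, delta_c = 1,
                                calibration = calibration)$interface_flux
  j_target / conductance
}

#' Convert a leaf export rate to interface flux densities
#'
#' Distributes the leaf-level carbon export over the BSC-IC interface area
#' and converts to molar flux densities, both as CH2O equivalents and as
#' sucrose.
#'
#' @param spec A [leaf_export_spec()].
#' @return A list with `mass_flux_g_m2_s`, `ch2o_mol_m2_s`,
#'   `sucrose_mol_m2_s` and a `units` note.
#' @examples
#' leaf_export_to_interface_flux(leaf_export_spec())
#' @export
leaf_export_to_interface_flux <- function(spec = leaf_export_spec()) {
  stopifnot(inherits(spec, "leaf_export_spec"))
  # mg dm^-2 h^-1 over mm^2 dm^-2: g per m^2 of interface per s
  mass_g_per_s_per_m2 <- (spec$export_rate * 1e-3) /
    (spec$interface_area_per_leaf_area * 1e-6) / 3600
  list(mass_flux_g_m2_s = mass_g_per_s_per_m2,
       ch2o_mol_m2_s = mass_g_per_s_per_m2 / spec$molar_mass_ch2o,
       sucrose_mol_m2_s = mass_g_per_s_per_m2 / spec$molar_mass_sucrose,
       units = "mol m-2 s-1 across the BSC-IC interface")
}

#' Flux-versus-potential profile for a set of solutes
#'
#' Tabulates the wall-level interface flux over a grid of concentration
#' potentials for each solute (the flux-potential curves used to compare
#' substructures against literature flux constraints). The profile is
#' strictly linear through the origin; (0, 0) is always included.
#'
#' @param geometry A `pd_geometry` with an absolute cross-section.
#' @param interface An [interface_spec()].
#' @param solutes Named list of [solute_spec()].
#' @param delta_c_grid Non-negative potentials, mM.
#' @param scenario Optional [transport_scenario()]; its potentials and flux
#'   targets are attached as attributes for annotation.
#' @param calibration See [interface_flux()].
#' @return A data.frame with columns `solute`, `delta_c_mM`,
#'   `interface_flux_mol_m2_s`, `geometry_id`.
#' @export
flux_potential_profile <- function(geometry, interface,
                                   solutes = default_solutes(),
                                   delta_c_grid = c(1, 10, 60, 67, 100, 334, 1000),
                                   scenario = NULL, calibration = 1) {
  check_nonnegative(delta_c_grid, "delta_c_grid")
  grid <- sort(unique(c(0, delta_c_grid)))
  model <- class(geometry)[1]
  rows <- list()
  for (nm in names(solutes)) {
    fx1 <- interface_flux(geometry, interface, solutes[[nm]], delta_c = 1,
                          calibration = calibration)$interface_flux
    rows[[nm]] <- data.frame(solute = nm, delta_c_mM = grid,
                             interface_flux_mol_m2_s = fx1 * grid,
                             geometry_id = model)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(scenario)) {
    attr(out, "scenario_potentials") <- scenario$potentials
    attr(out, "flux_targets") <- scenario$flux_targets
  }
  out
}
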