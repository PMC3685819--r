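# Pore-substructure hypotheses and the wall-interface description.
# All linear dimensions at this boundary are in angstrom (geometry) or
# micrometre (interface); see the vignette for the unit conventions.

#' Sub-nano channel substructure
#'
#' A plasmodesma whose cytoplasmic passage is a bundle of identical
#' cylindrical channels.
#'
#' @param pore_radius Channel radius, angstrom.
#' @param channels_per_pd Number of channels per plasmodesma (integer >= 1).
#' @return A `pd_geometry` object of subclass `channel_geometry`.
#' @examples
#' channel_geometry(6.4, channels_per_pd = 9)
#' @export
channel_geometry <- function(pore_radius, channels_per_pd = 1L) {
  check_positive(pore_radius, "pore_radius")
  if (!is.numeric(channels_per_pd) || length(channels_per_pd) != 1L ||
      channels_per_pd < 1 || channels_per_pd != round(channels_per_pd))
    stop_invalid("channels_per_pd", "must be an integer >= 1")
  structure(list(pore_radius = pore_radius,
                 channels_per_pd = as.integer(channels_per_pd)),
            class = c("channel_geometry", "pd_geometry"))
}

#' Annular slit (cytoplasmic sleeve) substructure
#'
#' The cytoplasmic sleeve between plasma membrane and desmotuble is a thin
#' annulus whose width is small against its diameter, so it is modelled as
#' a slit of half-width `half_width`.
#'
#' @param half_width Slit half-width, angstrom.
#' @param slit_circumference Cross-section length of the annular slit per
#'   plasmodesma, angstrom; only needed when an absolute open area (and
#'   hence an absolute interface flux) is requested. Default `NA`.
#' @return A `pd_geometry` object of subclass `slit_geometry`.
#' @export
slit_geometry <- function(half_width, slit_circumference = NA_real_) {
  check_positive(half_width, "half_width")
  if (!is.na(slit_circumference)) check_positive(slit_circumference, "slit_circumference")
  structure(list(half_width = half_width,
                 slit_circumference = slit_circumference),
            class = c("slit_geometry", "pd_geometry"))
}

#' Hydrogel substructure
#'
#' The plasmodesmal passage is filled by a polymer-fiber meshwork
#' (a hydrogel), characterised by polymer volume fraction and fiber
#' radius. The lambda convention is configurable: the hydrogel hindrance
#' expression uses a relative size lambda that published accounts define
#' inconsistently, so both `solute_over_fiber` (r_s/r_f, the default) and
#' `fiber_over_solute` (r_f/r_s) are supported.
#'
#' @param volume_fraction Polymer volume fraction Phi in \[0, 1).
#' @param fiber_radius Polymer fiber radius, angstrom (default 15,
#'   anticipating protein filaments similar to nuclear-pore FG repeats).
#' @param lambda_convention `"solute_over_fiber"` or `"fiber_over_solute"`.
#' @param cross_section_radius Radius of the gel-filled plasmodesmal
#'   cross-section, angstrom; only needed for absolute interface flux.
#' @return A `pd_geometry` object of subclass `hydrogel_geometry`.
#' @export
hydrogel_geometry <- function(volume_fraction, fiber_radius = 15,
                              lambda_convention = c("solute_over_fiber",
                                                    "fiber_over_solute"),
                              cross_section_radius = NA_real_) {
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      is.na(volume_fraction) || volume_fraction < 0 || volume_fraction >= 1)
    stop_invalid("volume_fraction", "must lie in [0, 1)")
  check_positive(fiber_radius, "fiber_radius")
  lambda_convention <- match.arg(lambda_convention)
  if (!is.na(cross_section_radius))
    check_positive(cross_section_radius, "cross_section_radius")
  structure(list(volume_fraction = volume_fraction,
                 fiber_radius = fiber_radius,
                 lambda_convention = lambda_convention,
                 cross_section_radius = cross_section_radius),
            class = c("hydrogel_geometry", "pd_geometry"))
}

#' The BSC-IC wall interface
#'
#' Describes the cell-wall interface between bundle sheath cell and
#' intermediary cell: plasmodesmal density, the length of the restricting
#' neck region (the diffusion distance), and the experimentally measured
#' wall-level effective diffusion coefficient used as matching target.
#'
#' @param pd_density Plasmodesmata per um^2 of wall (default 14, IC-side
#'   branches, taken as transport-limiting).
#' @param neck_length Length of the restricting neck region, um (default 0.18).
#' @param wall_thickness Wall thickness for the mesophyll-mesophyll
#'   comparison, um (default 0.1).
#' @param measured_deff Measured effective diffusion coefficient, um^2 s^-1
#'   (default 0.41, fluorescein across the BSC-IC wall).
#' @return An object of class `interface_spec`.
#' @examples
#' interface_spec()
#' @export
interface_spec <- function(pd_density = 14, neck_length = 0.18,
                           wall_thickness = 0.1, measured_deff = 0.41) {
  check_positive(pd_density, "pd_density")
  check_positive(neck_length, "neck_length")
  check_positive(wall_thickness, "wall_thickness")
  check_positive(measured_deff, "measured_deff")
  structure(list(pd_density = pd_density, neck_length = neck_length,
                 wall_thickness = wall_thickness, measured_deff = measured_deff),
            class = "interface_spec")
}

# reference constant: wall-level diffusion across a mesophyll-mesophyll
# interface (um^2 s^-1 across a 0.1 um wall), for comparison only
#' Mesophyll-mesophyll reference diffusion coefficient
#'
#' Stored reference value: ~0.5 um^2 s^-1 across a 0.1 um mesophyll wall.
#' @return Named numeric vector with elements `deff_um2_s` and
#'   `wall_thickness_um`.
#' @export
mesophyll_reference <- function() {
  c(deff_um2_s = 0.5, wall_thickness_um = 0.1)
}
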