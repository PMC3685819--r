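#' Physical constants for Stokes-Einstein calculations
#'
#' Bundles Boltzmann's constant, absolute temperature and dynamic viscosity
#' of the solvent. Defaults correspond to water at 298 K.
#'
#' @param boltzmann_constant Boltzmann's constant in J K^-1.
#' @param temperature Absolute temperature in K.
#' @param viscosity Dynamic viscosity in Pa s (0.89 centipoise = 8.9e-4 Pa s
#'   for water at 298 K).
#' @return An object of class `physical_constants`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function(boltzmann_constant = 1.38e-23,
                               temperature = 298,
                               viscosity = 8.9e-4) {
  check_positive(boltzmann_constant, "boltzmann_constant")
  check_positive(temperature, "temperature")
  check_positive(viscosity, "viscosity")
  structure(list(boltzmann_constant = boltzmann_constant,
                 temperature = temperature,
                 viscosity = viscosity),
            class = "physical_constants")
}

#' Hydrodynamic radius from a bulk diffusion coefficient
#'
#' Stokes-Einstein relation: the radius of the sphere that diffuses at the
#' same rate as the molecule, \eqn{R_{hyd} = kT / (6 \pi \eta D)}.
#'
#' @param d_bulk Diffusion coefficient in bulk water, m^2 s^-1.
#' @param constants A [physical_constants()] object.
#' @return Hydrodynamic radius in angstrom.
#' @examples
#' stokes_einstein_radius(5.23e-10)  # sucrose
#' @export
stokes_einstein_radius <- function(d_bulk, constants = physical_constants()) {
  check_positive(d_bulk, "d_bulk")
  stopifnot(inherits(constants, "physical_constants"))
  r_m <- constants$boltzmann_constant * constants$temperature /
    (6 * pi * constants$viscosity * d_bulk)
  r_m * 1e10
}

#' Bulk diffusion coefficient from a hydrodynamic radius
#'
#' Algebraic inverse of [stokes_einstein_radius()].
#'
#' @param r_hyd Hydrodynamic radius in angstrom.
#' @inheritParams stokes_einstein_radius
#' @return Diffusion coefficient in m^2 s^-1.
#' @export
stokes_einstein_diffusivity <- function(r_hyd, constants = physical_constants()) {
  check_positive(r_hyd, "r_hyd")
  stopifnot(inherits(constants, "physical_constants"))
  constants$boltzmann_constant * constants$temperature /
    (6 * pi * constants$viscosity * (r_hyd * 1e-10))
}

#' Define a diffusing solute
#'
#' @param name Identifier, e.g. `"sucrose"`.
#' @param d_water Diffusion coefficient in bulk water, m^2 s^-1.
#' @param r_hyd Hydrodynamic radius, angstrom.
#' @param cytosol_factor Dimensionless divisor for the cytosolic diffusion
#'   coefficient; cytosolic diffusion is taken as `d_water / cytosol_factor`
#'   (default 2, i.e. half the rate in water).
#' @return An object of class `solute_spec`.
#' @examples
#' solute_spec("sucrose", d_water = 5.23e-10, r_hyd = 4.38)
#' @export
solute_spec <- function(name, d_water, r_hyd, cytosol_factor = 2) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_invalid("name", "must be a non-empty string")
  check_positive(d_water, "d_water")
  check_positive(r_hyd, "r_hyd")
  if (!is.numeric(cytosol_factor) || cytosol_factor < 1)
    stop_invalid("cytosol_factor", "must be >= 1")
  structure(list(name = name, d_water = d_water, r_hyd = r_hyd,
                 cytosol_factor = cytosol_factor),
            class = "solute_spec")
}

#' Cytosolic diffusion coefficient of a solute
#'
#' @param solute A [solute_spec()].
#' @return Diffusivity in m^2 s^-1 (`d_water / cytosol_factor`).
#' @export
d_cytosol <- function(solute) {
  stopifnot(inherits(solute, "solute_spec"))
  solute$d_water / solute$cytosol_factor
}

#' Default solute registry
#'
#' Sugars of the raffinose-family-oligosaccharide loading pathway plus the
#' symplasmic tracer fluorescein. Bulk diffusivities are standard literature
#' defaults (config-overridable, not measured here). Sugar radii are the
#' values recovered by [recover_radius_from_cutoff()] from the printed
#' 1000-fold slit cut-off half-widths (4.4, 5.4, 6.2 angstrom); fluorescein
#' uses its molecular-model radius of 4.9 angstrom.
#'
#' @param cytosol_factor Divisor applied to all bulk diffusivities to obtain
#'   cytosolic values; default 2.
#' @return A named list of [solute_spec()] objects
#'   (sucrose, raffinose, stachyose, fluorescein).
#' @examples
#' names(default_solutes())
#' @export
default_solutes <- function(cytosol_factor = 2) {
  list(
    sucrose     = solute_spec("sucrose",     5.23e-10, 4.38, cytosol_factor),
    raffinose   = solute_spec("raffinose",   4.34e-10, 5.37, cytosol_factor),
    stachyose   = solute_spec("stachyose",   3.87e-10, 6.17, cytosol_factor),
    fluorescein = solute_spec("fluorescein", 4.25e-10, 4.90, cytosol_factor)
  )
}

#' Recover a solute radius from a printed hindrance cut-off
#'
#' Given the pore dimension (channel radius or slit half-width) at which
#' diffusion is reduced by a stated factor, solve the corresponding
#' hindrance model for the relative size lambda* with
#' \eqn{H(\lambda^*) = 1/\mathrm{reduction}} and return
#' `lambda* * cutoff_dimension`, the solute radius consistent with that
#' cut-off.
#'
#' @param model `"channel"` or `"slit"`.
#' @param cutoff_dimension Pore radius or slit half-width, angstrom.
#' @param reduction_factor Fold-reduction of diffusivity at the cut-off
#'   (e.g. 1000); must be > 1.
#' @return Solute radius in angstrom.
#' @examples
#' recover_radius_from_cutoff("slit", 6.2, 1000)  # stachyose, ~6.17 A
#' @export
recover_radius_from_cutoff <- function(model = c("channel", "slit"),
                                       cutoff_dimension, reduction_factor) {
  model <- match.arg(model)
  check_positive(cutoff_dimension, "cutoff_dimension")
  if (!is.numeric(reduction_factor) || length(reduction_factor) != 1L ||
      reduction_factor <= 1)
    stop_invalid("reduction_factor", "must be > 1 (H = 1 only at lambda = 0)")
  h_fun <- if (model == "channel") hindrance_channel else hindrance_slit
  target <- 1 / reduction_factor
  f <- function(l) h_fun(l) - target
  lo <- 1e-12; hi <- 1 - 1e-12
  if (f(lo) < 0 || f(hi) > 0)
    stop("solver failure: no sign change in lambda bracket (0, 1)", call. = FALSE)
  lam <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  lam * cutoff_dimension
}

#' Read or write a solute registry file
#'
#' Delimited text with header columns `name`, `d_water_m2_per_s`,
#' `r_hyd_angstrom`, `cytosol_factor` ("." decimal separator, UTF-8).
#'
#' @param path File path.
#' @return `read_solute_registry()` returns a named list of [solute_spec()];
#'   `write_solute_registry()` returns `path` invisibly.
#' @export
read_solute_registry <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("parse error in solute registry '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  needed <- c("name", "d_water_m2_per_s", "r_hyd_angstrom", "cytosol_factor")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("parse error in solute registry '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("solute registry '%s' is empty", path), call. = FALSE)
  if (anyDuplicated(df$name))
    stop(sprintf("solute registry '%s': duplicated solute name(s) at line(s) %s",
                 path, paste(which(duplicated(df$name)) + 1L, collapse = ", ")),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      solute_spec(df$name[i], df$d_water_m2_per_s[i], df$r_hyd_angstrom[i],
                  df$cytosol_factor[i]),
      error = function(e) stop(sprintf(
        "parse error in solute registry '%s' line %d: %s",
        path, i + 1L, conditionMessage(e)), call. = FALSE))
  })
  stats::setNames(out, df$name)
}

#' @param solutes A named list of [solute_spec()] objects.
#' @rdname read_solute_registry
#' @export
write_solute_registry <- function(solutes, path) {
  df <- data.frame(
    name = vapply(solutes, `[[`, character(1), "name"),
    d_water_m2_per_s = vapply(solutes, `[[`, numeric(1), "d_water"),
    r_hyd_angstrom = vapply(solutes, `[[`, numeric(1), "r_hyd"),
    cytosol_factor = vapply(solutes, `[[`, numeric(1), "cytosol_factor"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
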