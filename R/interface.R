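# Aggregation of per-pore hindrance to the wall-interface level, and
# inversion against the measured effective diffusion coefficient.

ANG_TO_UM <- 1e-4   # 1 angstrom = 1e-4 um
M2S_TO_UM2S <- 1e12 # m^2 s^-1 -> um^2 s^-1

# per-PD open cross-sectional area in um^2 (NA when the geometry lacks the
# parameter needed for an absolute area)
pd_open_area_um2 <- function(geometry) {
  if (inherits(geometry, "channel_geometry")) {
    geometry$channels_per_pd * pi * (geometry$pore_radius * ANG_TO_UM)^2
  } else if (inherits(geometry, "slit_geometry")) {
    if (is.na(geometry$slit_circumference)) return(NA_real_)
    geometry$slit_circumference * 2 * geometry$half_width * ANG_TO_UM^2
  } else if (inherits(geometry, "hydrogel_geometry")) {
    if (is.na(geometry$cross_section_radius)) return(NA_real_)
    pi * (geometry$cross_section_radius * ANG_TO_UM)^2
  } else stop("unknown geometry class", call. = FALSE)
}

#' Interface-level effective diffusion coefficient
#'
#' Aggregates the per-pore hindrance of one plasmodesmal substructure to a
#' wall-level effective diffusion coefficient. Two scalings are provided:
#'
#' * `"literal"`: `D_eff = x * n * H * D_cyt` with x the PD density
#'   (per um^2), n the channels per PD (1 for slit/hydrogel) and D_cyt the
#'   cytosolic diffusivity in um^2 s^-1. This is the aggregation formula
#'   as classically stated; note that with strict SI inputs it
#'   over-predicts measured wall-level coefficients by roughly two orders
#'   of magnitude (see the vignette), which is why the area-weighted mode
#'   and a calibration scalar exist.
#' * `"area"`: replaces `x * n` by the open-pore area fraction of the wall,
#'   `x` times the per-PD open cross-section.
#'
#' @param interface An [interface_spec()].
#' @param geometry A `pd_geometry`.
#' @param solute A [solute_spec()].
#' @param scale_mode `"literal"` or `"area"`.
#' @param calibration Positive scalar multiplying the result (default 1);
#'   exposed so the classical literal-mode curves can be reproduced.
#' @return Effective diffusion coefficient in um^2 s^-1, with attributes
#'   `scale_mode`, `calibration`, `hindrance`, `lambda_ratio`.
#' @examples
#' effective_diffusion(interface_spec(), channel_geometry(6.4, 9),
#'                     default_solutes()$fluorescein)
#' @export
effective_diffusion <- function(interface, geometry, solute,
                                scale_mode = c("literal", "area"),
                                calibration = 1) {
  stopifnot(inherits(interface, "interface_spec"))
  scale_mode <- match.arg(scale_mode)
  check_positive(calibration, "calibration")
  hf <- hindrance_factor(geometry, solute)
  d_cyt_um <- d_cytosol(solute) * M2S_TO_UM2S
  if (scale_mode == "literal") {
    note_once("literal_mode", paste(
      "effective_diffusion: literal scale mode aggregates per-pore hindrance",
      "without an open-area fraction and over-predicts measured wall-level",
      "coefficients by ~10^2; see the package vignette."))
    n <- if (inherits(geometry, "channel_geometry")) geometry$channels_per_pd else 1
    deff <- interface$pd_density * n * hf$hindrance * d_cyt_um
  } else {
    area <- pd_open_area_um2(geometry)
    if (is.na(area))
      stop(paste("missing parameter: area-weighted mode needs",
                 "slit_circumference (slit) or cross_section_radius (hydrogel)"),
           call. = FALSE)
    deff <- interface$pd_density * area * hf$hindrance * d_cyt_um
  }
  if (calibration != 1)
    note_once("calibration", sprintf(
      "effective_diffusion: calibration scalar %g != 1 in effect.", calibration))
  structure(deff * calibration, scale_mode = scale_mode,
            calibration = calibration, hindrance = hf$hindrance,
            lambda_ratio = hf$lambda_ratio)
}

#' Channel configurations matching a target effective diffusion coefficient
#'
#' For each candidate number of channels per plasmodesma, root-finds the
#' channel radius at which the predicted wall-level effective diffusion
#' coefficient equals `target_deff` (relative tolerance 1e-6). Counts with
#' no solution inside the radius bracket are reported as unmatched rather
#' than dropped.
#'
#' @inheritParams effective_diffusion
#' @param target_deff Target effective diffusion coefficient, um^2 s^-1.
#' @param channel_counts Integer vector of channels-per-PD candidates.
#' @return A data.frame with columns `channels_per_pd`,
#'   `pore_radius_angstrom`, `predicted_deff_um2_s`, `matched`, `note`.
#' @examples
#' matching_curve(interface_spec(), 0.41, default_solutes()$fluorescein,
#'                channel_counts = c(1, 4, 9))
#' @export
matching_curve <- function(interface, target_deff, solute,
                           channel_counts = 1:20,
                           scale_mode = c("literal", "area"),
                           calibration = 1) {
  check_positive(target_deff, "target_deff")
  scale_mode <- match.arg(scale_mode)
  rows <- lapply(channel_counts, function(n) {
    f <- function(r) {
      as.numeric(effective_diffusion(interface, channel_geometry(r, n), solute,
                                     scale_mode, calibration)) - target_deff
    }
    lo <- solute$r_hyd * (1 + 1e-9); hi <- 1e4
    if (f(hi) < 0) {
      return(data.frame(channels_per_pd = n, pore_radius_angstrom = NA_real_,
                        predicted_deff_um2_s = NA_real_, matched = FALSE,
                        note = "target unreachable: D_eff below target even as hindrance vanishes"))
    }
    if (f(lo) > 0) {
      return(data.frame(channels_per_pd = n, pore_radius_angstrom = NA_real_,
                        predicted_deff_um2_s = NA_real_, matched = FALSE,
                        note = "target unreachable: D_eff above target over the whole bracket"))
    }
    r <- stats::uniroot(f, c(lo, hi), tol = 1e-10 * solute$r_hyd,
                        maxiter = 500)$root
    pred <- as.numeric(effective_diffusion(interface, channel_geometry(r, n),
                                           solute, scale_mode, calibration))
    data.frame(channels_per_pd = n, pore_radius_angstrom = r,
               predicted_deff_um2_s = pred, matched = TRUE, note = "")
  })
  out <- do.call(rbind, rows)
  attr(out, "scale_mode") <- scale_mode
  attr(out, "calibration") <- calibration
  out
}

#' Cross-configuration consistency of matched substructures
#'
#' For a set of substructure hypotheses that were each tuned to match the
#' same measured wall-level diffusion, reports the per-PD conductance
#' factor for a given solute (n * H for channels, H for slit and hydrogel)
#' and the maximum pairwise ratio among conducting configurations.
#' Configurations with H = 0 are flagged as non-conducting and excluded
#' from the ratio.
#'
#' @param configs List of `pd_geometry` objects (length >= 2).
#' @param interface An [interface_spec()] (carried for metadata).
#' @param solute A [solute_spec()].
#' @return A list with `table` (data.frame: `model`, `conductance_factor`,
#'   `conducting`) and `max_pairwise_ratio`.
#' @examples
#' cross_configuration_consistency(
#'   list(channel_geometry(6.4, 9), slit_geometry(5.2)),
#'   interface_spec(), default_solutes()$fluorescein)
#' @export
cross_configuration_consistency <- function(configs, interface, solute) {
  if (!is.list(configs) || length(configs) < 2L)
    stop_invalid("configs", "must be a list of at least two geometries")
  tab <- do.call(rbind, lapply(configs, function(g) {
    hf <- hindrance_factor(g, solute)
    n <- if (inherits(g, "channel_geometry")) g$channels_per_pd else 1
    data.frame(model = hf$model_id, conductance_factor = n * hf$hindrance,
               conducting = hf$hindrance > 0)
  }))
  cf <- tab$conductance_factor[tab$conducting]
  ratio <- if (length(cf) >= 2L) max(cf) / min(cf) else NA_real_
  list(table = tab, max_pairwise_ratio = ratio)
}
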