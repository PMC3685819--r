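# Closed-form hindrance factors H = D_a/D0 for the three substructure
# hypotheses. The channel and slit forms are centerline-averaged
# hydrodynamic results for long pores; both are exact coefficient-sum
# identities at lambda = 1 (H = 0) and unhindered at lambda = 0 (H = 1).

# raw values slightly below 0 from floating-point cancellation near
# lambda -> 1 are clamped; anything below this is a real evaluation bug
.clamp_floor <- -1e-4

clamp_h <- function(h, where) {
  bad <- h < .clamp_floor
  if (any(bad))
    stop(sprintf("internal consistency error: %s produced %g (< %g)",
                 where, min(h), .clamp_floor), call. = FALSE)
  pmin(pmax(h, 0), 1)
}

#' Hindrance factor in a cylindrical sub-nano channel
#'
#' Centerline-approximation hindrance factor for a neutral sphere of
#' radius r_s diffusing along a long cylindrical pore of radius r_p,
#' as a function of lambda = r_s / r_p:
#' \deqn{H = 1 + \tfrac{9}{8}\lambda\ln\lambda - 1.56034\lambda
#'   + 0.528155\lambda^2 + 1.91521\lambda^3 - 2.81903\lambda^4
#'   + 0.270788\lambda^5 + 1.10115\lambda^6 - 0.435933\lambda^7}
#' For lambda >= 1 the solute cannot enter and H = 0.
#'
#' @param lambda_ratio Relative solute size r_s/r_p (vectorized, >= 0).
#' @return Hindrance factor H in \[0, 1\].
#' @examples
#' hindrance_channel(c(0, 0.5, 1))
#' @export
hindrance_channel <- function(lambda_ratio) {
  check_nonnegative(lambda_ratio, "lambda_ratio")
  l <- lambda_ratio
  h <- ifelse(l >= 1, 0, {
    ll <- ifelse(l > 0, l * log(l), 0)
    1 + 9 / 8 * ll - 1.56034 * l + 0.528155 * l^2 + 1.91521 * l^3 -
      2.81903 * l^4 + 0.270788 * l^5 + 1.10115 * l^6 - 0.435933 * l^7
  })
  clamp_h(h, "hindrance_channel")
}

#' Hindrance factor in a slit
#'
#' Analytical hindrance factor for a neutral sphere diffusing in a slit of
#' half-width h, with lambda = r_s / h:
#' \deqn{H = 1 + \tfrac{9}{16}\lambda\ln\lambda - 1.19358\lambda
#'   + 0.4285\lambda^3 - 0.3192\lambda^4 + 0.08428\lambda^5}
#' (no quadratic term). For lambda >= 1, H = 0.
#'
#' @inheritParams hindrance_channel
#' @return Hindrance factor H in \[0, 1\].
#' @examples
#' hindrance_slit(c(0, 0.5, 1))
#' @export
hindrance_slit <- function(lambda_ratio) {
  check_nonnegative(lambda_ratio, "lambda_ratio")
  l <- lambda_ratio
  h <- ifelse(l >= 1, 0, {
    ll <- ifelse(l > 0, l * log(l), 0)
    1 + 9 / 16 * ll - 1.19358 * l + 0.4285 * l^3 - 0.3192 * l^4 + 0.08428 * l^5
  })
  clamp_h(h, "hindrance_slit")
}

#' Hindrance factor in a hydrogel
#'
#' Combined obstruction-plus-hydrodynamic hindrance of a polymer-fiber
#' meshwork with volume fraction Phi and fiber radius r_f:
#' \deqn{H = \exp(-0.84 f^{1.09}) \times
#'   \exp\big(-(3.727 - 2.46\lambda + 0.822\lambda^2)\,
#'   \Phi^{(0.358 + 0.366\lambda - 0.0939\lambda^2)}\big)}
#' with adjusted volume fraction \eqn{f = (1 + r_s/r_f)^2 \Phi} and lambda
#' per the geometry's configured convention (default r_s/r_f).
#'
#' @param solute_radius Solute hydrodynamic radius, angstrom.
#' @param geometry A [hydrogel_geometry()].
#' @return Hindrance factor H in (0, 1\].
#' @examples
#' hindrance_hydrogel(5, hydrogel_geometry(0.2))
#' @export
hindrance_hydrogel <- function(solute_radius, geometry) {
  check_positive(solute_radius, "solute_radius")
  stopifnot(inherits(geometry, "hydrogel_geometry"))
  phi <- geometry$volume_fraction
  rf <- geometry$fiber_radius
  lam <- switch(geometry$lambda_convention,
                solute_over_fiber = solute_radius / rf,
                fiber_over_solute = rf / solute_radius)
  f <- (1 + solute_radius / rf)^2 * phi
  if (phi == 0) return(1)
  obstruction <- exp(-0.84 * f^1.09)
  hydrodynamic <- exp(-(3.727 - 2.46 * lam + 0.822 * lam^2) *
                        phi^(0.358 + 0.366 * lam - 0.0939 * lam^2))
  obstruction * hydrodynamic
}

# lambda for a solute radius in a channel/slit geometry
geometry_lambda <- function(geometry, solute_radius) {
  if (inherits(geometry, "channel_geometry")) solute_radius / geometry$pore_radius
  else if (inherits(geometry, "slit_geometry")) solute_radius / geometry$half_width
  else stop("geometry_lambda is defined for channel and slit geometries only",
            call. = FALSE)
}

#' Evaluate hindrance of a solute in any pore geometry
#'
#' Dispatches on the geometry subclass and returns the relative size
#' lambda, the hindrance factor H, the apparent diffusivity H * D0 and a
#' model identifier.
#'
#' @param geometry A `pd_geometry` object.
#' @param solute A [solute_spec()].
#' @param d0 Reference diffusivity (m^2 s^-1) used for the apparent
#'   diffusivity; default is the solute's cytosolic diffusivity.
#' @return A list with elements `lambda_ratio`, `hindrance`,
#'   `apparent_diffusivity`, `model_id`.
#' @examples
#' hindrance_factor(slit_geometry(6.1), default_solutes()$sucrose)
#' @export
hindrance_factor <- function(geometry, solute, d0 = d_cytosol(solute)) {
  stopifnot(inherits(geometry, "pd_geometry"), inherits(solute, "solute_spec"))
  if (inherits(geometry, "hydrogel_geometry")) {
    lam <- switch(geometry$lambda_convention,
                  solute_over_fiber = solute$r_hyd / geometry$fiber_radius,
                  fiber_over_solute = geometry$fiber_radius / solute$r_hyd)
    h <- hindrance_hydrogel(solute$r_hyd, geometry)
    model <- "hydrogel"
  } else {
    lam <- geometry_lambda(geometry, solute$r_hyd)
    h <- if (inherits(geometry, "channel_geometry")) hindrance_channel(lam)
         else hindrance_slit(lam)
    model <- if (inherits(geometry, "channel_geometry")) "channel" else "slit"
  }
  list(lambda_ratio = lam, hindrance = h, apparent_diffusivity = h * d0,
       model_id = model)
}

#' Pore dimension at which a solute reaches a target hindrance
#'
#' Inverts the channel or slit hindrance curve: finds the pore radius
#' (channel) or half-width (slit) at which H for a solute of radius
#' `solute_radius` equals `target_h`. Root-found on the dimension over the
#' bracket \[r_s (1 + 1e-6), 1e4 angstrom\]; H at the upper bracket still
#' below target is reported as no finite solution.
#'
#' @param model `"channel"` or `"slit"`.
#' @param solute_radius Solute radius, angstrom.
#' @param target_h Target hindrance factor, strictly between 0 and 1.
#' @return Dimension in angstrom.
#' @examples
#' invert_geometry("slit", 6.1, 1e-3)  # ~6.13 A half-width
#' @export
invert_geometry <- function(model = c("channel", "slit"), solute_radius,
                            target_h) {
  model <- match.arg(model)
  check_positive(solute_radius, "solute_radius")
  if (!is.numeric(target_h) || length(target_h) != 1L || target_h <= 0)
    stop_invalid("target_h", "must be strictly positive")
  if (target_h >= 1)
    stop("no finite solution: hindrance below 1 for every finite dimension",
         call. = FALSE)
  h_fun <- if (model == "channel") hindrance_channel else hindrance_slit
  # solve in lambda-space (equivalent bracket, much better conditioned):
  # dimension in [r_s (1+1e-6), 1e4] <=> lambda in [r_s/1e4, 1/(1+1e-6)]
  lam_lo <- solute_radius / 1e4
  lam_hi <- 1 / (1 + 1e-6)
  if (h_fun(lam_lo) < target_h)
    stop(sprintf(
      "no finite solution: H at the bracket ceiling (1e4 angstrom) is still below %g",
      target_h), call. = FALSE)
  if (h_fun(lam_hi) > target_h)
    stop("solver failure: no sign change in dimension bracket", call. = FALSE)
  lam <- stats::uniroot(function(l) h_fun(l) - target_h, c(lam_lo, lam_hi),
                        tol = 1e-13, maxiter = 200)$root
  solute_radius / lam
}

#' Relative hindrance of two solutes in the same geometry
#'
#' Ratio H_b / H_a: how much more hindered solute `a` is than solute `b`
#' (a value above 1 when `a` is the larger, more hindered solute).
#'
#' @param geometry A `pd_geometry`.
#' @param solute_a,solute_b [solute_spec()] objects; `a` is the solute whose
#'   extra hindrance is being quantified (typically the larger one).
#' @return Dimensionless ratio >= 0; `Inf` (with a warning) when `a` is
#'   fully blocked but `b` is not.
#' @examples
#' s <- default_solutes()
#' relative_hindrance(slit_geometry(6.1), s$raffinose, s$sucrose)  # ~3.2
#' @export
relative_hindrance <- function(geometry, solute_a, solute_b) {
  h_a <- hindrance_factor(geometry, solute_a)$hindrance
  h_b <- hindrance_factor(geometry, solute_b)$hindrance
  if (h_a == 0 && h_b == 0)
    stop("undefined ratio: both solutes are fully blocked (H = 0)", call. = FALSE)
  if (h_a == 0) {
    warning("solute_a is fully blocked (H = 0); returning Inf", call. = FALSE)
    return(Inf)
  }
  h_b / h_a
}

#' Hindrance curves across pore dimensions
#'
#' Tabulates H for each solute over a grid of pore dimensions, per model,
#' reproducing the hindrance-versus-dimension curves used to compare the
#' three substructure hypotheses. For `"hydrogel"` the dimension axis is
#' the polymer volume fraction.
#'
#' @param solutes Named list of [solute_spec()].
#' @param dimensions Numeric grid: angstrom for channel/slit, volume
#'   fraction in \[0, 1) for hydrogel.
#' @param models Character subset of `c("channel", "slit", "hydrogel")`.
#' @param fiber_radius Hydrogel fiber radius, angstrom.
#' @return A data.frame with columns `model`, `dimension_angstrom` (or
#'   volume fraction for the hydrogel rows), `solute`, `lambda`, `hindrance`.
#' @export
hindrance_curve <- function(solutes = default_solutes(),
                            dimensions,
                            models = c("channel", "slit", "hydrogel"),
                            fiber_radius = 15) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (model in models) {
    for (nm in names(solutes)) {
      s <- solutes[[nm]]
      for (d in dimensions) {
        if (model == "hydrogel") {
          if (d < 0 || d >= 1) next
          g <- hydrogel_geometry(d, fiber_radius = fiber_radius)
          hf <- hindrance_factor(g, s)
        } else {
          g <- if (model == "channel") channel_geometry(d) else slit_geometry(d)
          hf <- hindrance_factor(g, s)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, dimension_angstrom = d, solute = nm,
          lambda = hf$lambda_ratio, hindrance = hf$hindrance)
      }
    }
  }
  do.call(rbind, rows)
}
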