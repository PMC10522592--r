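# Optogenetic light-penetration utility: how deep below the fibre tip the
# 465 nm irradiance stays above the channelrhodopsin activation threshold.

#' Optical fibre and tissue parameters
#'
#' @param power_at_tip light power at the cannula tip, mW.
#' @param numerical_aperture fibre NA (dimensionless); must be below the
#'   tissue refractive index.
#' @param core_radius_mm fibre core radius, mm.  Note the radius/diameter
#'   convention explicitly: a "400 um" fibre has a 0.2 mm core radius, but
#'   pass 0.4 if a printed 400 um figure is to be read as the radius.
#' @param tissue_refractive_index refractive index of brain tissue
#'   (typically 1.35--1.36).
#' @param threshold_irradiance irradiance needed to activate the opsin,
#'   mW/mm^2 (1 mW/mm^2 for ChR2 with blue light).
#' @param scattering_mm Kubelka-Munk scattering coefficient of the tissue,
#'   1/mm (11.2 for mouse grey matter at 473 nm, 10.3 for rat).
#' @return object of class `fiber_spec`.
#' @export
fiber_spec <- function(power_at_tip, numerical_aperture, core_radius_mm,
                       tissue_refractive_index = 1.35,
                       threshold_irradiance = 1, scattering_mm = 11.2) {
  for (nm in c("power_at_tip", "numerical_aperture", "core_radius_mm",
               "tissue_refractive_index", "threshold_irradiance"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (numerical_aperture >= tissue_refractive_index)
    stop("numerical aperture must be below the tissue refractive index",
         call. = FALSE)
  if (scattering_mm < 0) stop("scattering_mm must be >= 0", call. = FALSE)
  structure(list(power_at_tip = power_at_tip,
                 numerical_aperture = numerical_aperture,
                 core_radius_mm = core_radius_mm,
                 tissue_refractive_index = tissue_refractive_index,
                 threshold_irradiance = threshold_irradiance,
                 scattering_mm = scattering_mm),
            class = "fiber_spec")
}

#' On-axis irradiance below a fibre tip
#'
#' Combines conical geometric spread -- half-angle
#' `theta = asin(NA / n_tissue)`, characteristic distance
#' `rho = r * sqrt((n/NA)^2 - 1)` -- with Kubelka-Munk scattering
#' attenuation `1 / (S z + 1)`:
#' `I(z) = I0 * rho^2 / ((S z + 1) (z + rho)^2)`, where
#' `I0 = P / (pi r^2)` is the irradiance at the fibre face.
#'
#' @param f a [fiber_spec()].
#' @param z depth below the fibre tip, mm (vectorised).
#' @param geometric_only if `TRUE`, disable scattering (S = 0).
#' @return irradiance in mW/mm^2.
#' @export
fiber_irradiance <- function(f, z, geometric_only = FALSE) {
  stopifnot(inherits(f, "fiber_spec"))
  r <- f$core_radius_mm
  I0 <- f$power_at_tip / (pi * r^2)
  rho <- r * sqrt((f$tissue_refractive_index / f$numerical_aperture)^2 - 1)
  S <- if (geometric_only) 0 else f$scattering_mm
  I0 * rho^2 / ((S * z + 1) * (z + rho)^2)
}

#' Light-activation depth
#'
#' Depth below the fibre tip at which the on-axis irradiance falls to the
#' opsin activation threshold, solved from [fiber_irradiance()].  Returns 0
#' when even the fibre-face irradiance is at or below threshold.
#'
#' @inheritParams fiber_irradiance
#' @param tol root tolerance, mm.
#' @return depth in mm.
#' @examples
#' # the canonical worked example: 1.46 mW, NA 0.57, 400 um figure read as
#' # the radius, n = 1.35, ChR2 threshold 1 mW/mm^2
#' activation_depth(fiber_spec(1.46, 0.57, 0.4))
#' @export
activation_depth <- function(f, geometric_only = FALSE, tol = 1e-9) {
  stopifnot(inherits(f, "fiber_spec"))
  if (fiber_irradiance(f, 0, geometric_only) <= f$threshold_irradiance)
    return(0)
  g <- function(z) fiber_irradiance(f, z, geometric_only) - f$threshold_irradiance
  upper <- 1
  while (g(upper) > 0) upper <- upper * 2
  uniroot(g, c(0, upper), tol = tol)$root
}
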