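#' Texture-derived water bounds for the monthly water budget
#'
#' Computes the bounds of the signed soil moisture deficit (SMD) from soil
#' texture. Volumetric water contents at field capacity (33 kPa) and at
#' saturation come from the Saxton-Rawls (2006) pedotransfer equations
#' (overridable by supplying `theta_fc`/`theta_sat` directly, e.g. from
#' laboratory retention data). The driest admissible deficits follow the
#' reference RothC clay formula, normalised to the simulated depth:
#' max SMD (vegetated) = (20.0 + 1.3 clay - 0.01 clay^2) depth / 23,
#' and the bare-soil cap is that value divided by 1.8.
#'
#' Sign convention: SMD > 0 is water missing below field capacity
#' (a deficit); SMD < 0 is excess water held between field capacity and
#' saturation; SMD = 0 is field capacity. The saturation bound is
#' smd_saturation = -(theta_sat - theta_fc) x depth x 10 mm.
#'
#' @param clay,sand,silt texture, percent by mass; must sum to 100 (+/- 1)
#' @param depth simulated topsoil depth, cm
#' @param om organic matter content used by the pedotransfer, percent by
#'   mass (default 2.5, typical of grassland topsoil)
#' @param theta_fc,theta_sat optional volumetric water contents
#'   (m3 m\eqn{^{-3}}) overriding the pedotransfer
#' @return an object of class `water_bounds`: `theta_fc`, `theta_sat`,
#'   `smd_saturation` (mm, negative), `max_smd_vegetated`,
#'   `max_smd_bare` (mm, positive), `depth` (cm)
#' @references Saxton K.E., Rawls W.J. (2006) Soil water characteristic
#'   estimates by texture and organic matter for hydrologic solutions.
#'   Soil Sci. Soc. Am. J. 70:1569-1578.
#' @export
pedotransfer_water <- function(clay, sand, silt = 100 - clay - sand,
                               depth = 23, om = 2.5,
                               theta_fc = NULL, theta_sat = NULL) {
  tot <- clay + sand + silt
  if (!is.finite(tot) || abs(tot - 100) > 1)
    stop("pedotransfer_water: clay + sand + silt must be ~100% (got ",
         round(tot, 2), ")")
  if (any(c(clay, sand, silt) < 0))
    stop("pedotransfer_water: negative texture fraction")
  if (!is.finite(depth) || depth <= 0)
    stop("pedotransfer_water: depth must be > 0")

  if (is.null(theta_fc) || is.null(theta_sat)) {
    S <- sand / 100; C <- clay / 100; OM <- om
    # Saxton-Rawls (2006): 33 kPa and saturation moisture, m3/m3
    th33t <- -0.251 * S + 0.195 * C + 0.011 * OM + 0.006 * S * OM -
      0.027 * C * OM + 0.452 * S * C + 0.299
    th33 <- th33t + (1.283 * th33t^2 - 0.374 * th33t - 0.015)
    ths33t <- 0.278 * S + 0.034 * C + 0.022 * OM - 0.018 * S * OM -
      0.027 * C * OM - 0.584 * S * C + 0.078
    ths33 <- ths33t + (0.636 * ths33t - 0.107)
    thsat <- th33 + ths33 - 0.097 * S + 0.043
    if (is.null(theta_fc)) theta_fc <- th33
    if (is.null(theta_sat)) theta_sat <- thsat
  }
  if (!(theta_sat > theta_fc && theta_fc > 0))
    stop("pedotransfer_water: need theta_sat > theta_fc > 0 (got ",
         round(theta_sat, 3), ", ", round(theta_fc, 3), ")")

  max_veg <- (20.0 + 1.3 * clay - 0.01 * clay^2) * depth / 23
  structure(list(
    theta_fc = theta_fc,
    theta_sat = theta_sat,
    smd_saturation = -(theta_sat - theta_fc) * depth * 10,
    max_smd_vegetated = max_veg,
    max_smd_bare = max_veg / 1.8,
    depth = depth
  ), class = "water_bounds")
}

#' Monthly update of the soil moisture deficit
#'
#' Advances the signed SMD by the month's water budget,
#' smd + 0.75 evap - rain, then clamps it to the admissible range. The
#' evaporation factor 0.75 converts open-pan evaporation to actual
#' evapotranspiration (set `evap_factor = 1` for Penman PET input). The dry
#' bound is the vegetated or bare maximum deficit as applicable; the wet
#' bound is the saturation SMD when `allow_saturation` is TRUE (excess
#' beyond saturation is shed as instantaneous runoff), otherwise zero —
#' the reference-model floor at field capacity.
#'
#' @param smd current signed deficit, mm
#' @param rain monthly precipitation, mm, >= 0
#' @param evap monthly open-pan evaporation (or PET), mm, >= 0
#' @param vegetated logical; growing vegetation this month?
#' @param bounds a [pedotransfer_water()] result
#' @param allow_saturation logical; track excess water down to saturation?
#' @param evap_factor multiplier on `evap` (0.75 open-pan, 1.0 PET)
#' @return the updated signed SMD, mm
#' @export
update_smd <- function(smd, rain, evap, vegetated, bounds,
                       allow_saturation = FALSE, evap_factor = 0.75) {
  if (any(!is.finite(c(smd, rain, evap))) || rain < 0 || evap < 0)
    stop("update_smd: rain and evap must be finite and >= 0")
  upper <- if (vegetated) bounds$max_smd_vegetated else bounds$max_smd_bare
  lower <- if (allow_saturation) bounds$smd_saturation else 0
  min(max(smd + evap_factor * evap - rain, lower), upper)
}

#' Moisture rate-modifying factor, optionally extended to saturation
#'
#' Factor `b` on the decomposition rates. Dry side (smd >= 0): 1.0 while
#' the deficit is below 0.444 of the maximum, then declining linearly to
#' 0.2 at the maximum deficit (reference RothC form). Wet side (smd < 0),
#' `extended` mode only: a linear decline from 1.0 at field capacity to a
#' minimum of 0.2 at saturation, representing oxygen limitation of
#' decomposition in waterlogged soil. In non-extended mode negative SMD is
#' unreachable (the water budget floors at field capacity).
#'
#' @param smd signed soil moisture deficit, mm
#' @param bounds a [pedotransfer_water()] result
#' @param extended logical; apply the wet-side decline to saturation?
#' @param vegetated logical; selects the applicable dry-side maximum
#' @return dimensionless factor in \[0.2, 1\], continuous in `smd`
#' @export
rate_modifier_moisture <- function(smd, bounds, extended = FALSE,
                                   vegetated = TRUE) {
  max_smd <- if (vegetated) bounds$max_smd_vegetated else bounds$max_smd_bare
  lower <- if (extended) bounds$smd_saturation else 0
  if (!is.finite(smd) || smd < lower - 1e-9 || smd > max_smd + 1e-9)
    stop("rate_modifier_moisture: smd = ", round(smd, 2),
         " outside [", round(lower, 2), ", ", round(max_smd, 2), "]")
  if (smd < 0) {
    # wet side: only reachable in extended mode
    1 - 0.8 * (smd / bounds$smd_saturation)
  } else if (smd <= 0.444 * max_smd) {
    1.0
  } else {
    0.2 + 0.8 * (max_smd - smd) / (max_smd - 0.444 * max_smd)
  }
}
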