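#' Root:shoot ratio as a function of nitrogen fertilisation
#'
#' Exponential N response for temperate grasslands:
#' R:S = 4.7375 exp(-0.0043 N), with N the annual nitrogen input in
#' kg N ha\eqn{^{-1}} yr\eqn{^{-1}}. Strictly decreasing: fertilisation
#' shifts allocation above ground.
#'
#' @param n_input annual N fertilisation, kg N ha\eqn{^{-1}}
#'   yr\eqn{^{-1}}, >= 0 (vectorised)
#' @return dimensionless root:shoot ratio
#' @export
root_shoot_ratio <- function(n_input) {
  if (any(!is.finite(n_input)) || any(n_input < 0))
    stop("root_shoot_ratio: n_input must be >= 0")
  4.7375 * exp(-0.0043 * n_input)
}

#' Plant residue specification for a grassland system
#'
#' Gathers the quantities and conversion factors that turn standing
#' above-ground biomass into the three plant-derived carbon input
#' components: above-ground residue, below-ground (root) residue and
#' rhizodeposition.
#'
#' Defaults encode the grassland assumptions: residues are 20% of
#' above-ground standing C under grazing and 30% x 50% = 15% under
#' cutting; 50% of root C turns over annually; net rhizodeposition is 50%
#' of root C; plant biomass is 45% carbon; the below-ground fibre fraction
#' exceeds the above-ground NDF by ~8 percentage points of lignin.
#'
#' @param above_ground_biomass standing above-ground biomass,
#'   Mg DM ha\eqn{^{-1}} yr\eqn{^{-1}}
#' @param management `"grazed"` or `"cut"`
#' @param n_input annual N fertilisation, kg N ha\eqn{^{-1}} yr\eqn{^{-1}}
#' @param rs_ratio_override optional measured root:shoot ratio; when NULL
#'   the ratio comes from [root_shoot_ratio()]
#' @param residue_fraction_above fraction of standing above-ground C that
#'   becomes residue; default 0.20 grazed, 0.15 cut
#' @param root_turnover annual fraction of root C turned over (default 0.5)
#' @param rhizo_to_root net rhizodeposition-to-root-C ratio (default 0.5)
#' @param c_concentration C fraction of dry biomass (default 0.45)
#' @param ndf_above neutral detergent fibre of above-ground tissue, percent
#' @param lignin_offset_below extra fibre percentage points below ground
#'   (default 8)
#' @param monthly_pattern 12 non-negative weights summing to 1 (default:
#'   the [european_grassland_pattern()] preset)
#' @param ndf_by_month optional 12 monthly NDF values (percent) giving
#'   month-on-month residue quality; overrides `ndf_above` per month
#' @return an object of class `plant_residue_spec`
#' @export
plant_residue_spec <- function(above_ground_biomass,
                               management = c("grazed", "cut"),
                               n_input,
                               rs_ratio_override = NULL,
                               residue_fraction_above = NULL,
                               root_turnover = 0.5,
                               rhizo_to_root = 0.5,
                               c_concentration = 0.45,
                               ndf_above = 50,
                               lignin_offset_below = 8,
                               monthly_pattern = european_grassland_pattern(),
                               ndf_by_month = NULL) {
  management <- match.arg(management)
  if (is.null(residue_fraction_above))
    residue_fraction_above <- if (management == "grazed") 0.20 else 0.30 * 0.50
  fr <- c(residue_fraction_above, root_turnover, rhizo_to_root,
          c_concentration)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("plant_residue_spec: fractions must be in [0, 1]")
  if (!is.finite(above_ground_biomass) || above_ground_biomass < 0)
    stop("plant_residue_spec: above_ground_biomass must be >= 0")
  if (!is.finite(n_input) || n_input < 0)
    stop("plant_residue_spec: n_input must be >= 0")
  if (!is.finite(ndf_above) || ndf_above < 0 || ndf_above > 100)
    stop("plant_residue_spec: ndf_above must be in [0, 100]")
  if (length(monthly_pattern) != 12 || any(monthly_pattern < 0) ||
      abs(sum(monthly_pattern) - 1) > 1e-9)
    stop("plant_residue_spec: monthly_pattern must be 12 non-negative ",
         "weights summing to 1")
  if (!is.null(ndf_by_month) && length(ndf_by_month) != 12)
    stop("plant_residue_spec: ndf_by_month must have 12 values")
  structure(list(above_ground_biomass = above_ground_biomass,
                 management = management, n_input = n_input,
                 rs_ratio_override = rs_ratio_override,
                 residue_fraction_above = residue_fraction_above,
                 root_turnover = root_turnover,
                 rhizo_to_root = rhizo_to_root,
                 c_concentration = c_concentration,
                 ndf_above = ndf_above,
                 lignin_offset_below = lignin_offset_below,
                 monthly_pattern = monthly_pattern,
                 ndf_by_month = ndf_by_month),
            class = "plant_residue_spec")
}

#' Seasonal input pattern preset for European managed grasslands
#'
#' Monthly weights for distributing annual plant C input: a May-June peak,
#' a shoulder through late summer and a flat November-February minimum.
#' A declared stand-in for the published European grassland pattern, which
#' is user-overridable via `monthly_pattern`.
#'
#' @return 12 weights summing to 1 (January first)
#' @export
european_grassland_pattern <- function() {
  c(0.03, 0.03, 0.06, 0.11, 0.15, 0.15, 0.12, 0.10, 0.10, 0.09, 0.03, 0.03)
}

#' Annual plant carbon input components
#'
#' Above-ground residue C = standing C x residue fraction; below-ground C
#' biomass = standing C x root:shoot ratio; root residue C = root C x
#' turnover; rhizodeposition C = root C x rhizodeposition ratio.
#'
#' @param spec a [plant_residue_spec()]
#' @return named list `c_above`, `c_below`, `c_rhizo`,
#'   Mg C ha\eqn{^{-1}} yr\eqn{^{-1}}
#' @export
annual_components <- function(spec) {
  stopifnot(inherits(spec, "plant_residue_spec"))
  above_c <- spec$above_ground_biomass * spec$c_concentration
  rs <- if (!is.null(spec$rs_ratio_override)) spec$rs_ratio_override
        else root_shoot_ratio(spec$n_input)
  below_c <- above_c * rs
  list(c_above = above_c * spec$residue_fraction_above,
       c_below = below_c * spec$root_turnover,
       c_rhizo = below_c * spec$rhizo_to_root)
}

#' Entry-pool quality per plant residue component
#'
#' Above-ground residue: RPM fraction = NDF/100 (fibre is the resistant
#' material), DPM = 1 - RPM. Below-ground residue: same with the fibre
#' raised by the below-ground lignin offset. Rhizodeposits: all DPM
#' (labile exudates).
#'
#' @param ndf_above above-ground NDF, percent
#' @param lignin_offset_below percentage points added to NDF below ground
#' @return list of per-component `c(f_dpm, f_rpm)`: `above`, `below`,
#'   `rhizo`
#' @export
component_quality <- function(ndf_above, lignin_offset_below = 8) {
  if (!is.finite(ndf_above) || ndf_above < 0 || ndf_above > 100)
    stop("component_quality: ndf_above must be in [0, 100]")
  ndf_below <- ndf_above + lignin_offset_below
  if (ndf_below < 0 || ndf_below > 100)
    stop("component_quality: below-ground fibre fraction outside [0, 100]")
  list(above = c(f_dpm = 1 - ndf_above / 100, f_rpm = ndf_above / 100),
       below = c(f_dpm = 1 - ndf_below / 100, f_rpm = ndf_below / 100),
       rhizo = c(f_dpm = 1, f_rpm = 0))
}

#' Distribute annual plant components over months with quality
#'
#' @param annual result of [annual_components()]
#' @param pattern 12 weights summing to 1
#' @param ndf_above annual above-ground NDF, percent (used when
#'   `ndf_by_month` is NULL)
#' @param ndf_by_month optional 12 monthly NDF values, percent
#' @param lignin_offset_below percentage points added below ground
#' @return a list of class `monthly_c_input` with 12-row matrices
#'   `amounts` (columns `c_above`, `c_below`, `c_rhizo`) and per-month
#'   quality matrices `f_dpm`, `f_rpm` (same columns)
#' @export
distribute_monthly <- function(annual, pattern = european_grassland_pattern(),
                               ndf_above = 50, ndf_by_month = NULL,
                               lignin_offset_below = 8) {
  if (length(pattern) != 12 || any(pattern < 0) ||
      abs(sum(pattern) - 1) > 1e-9)
    stop("distribute_monthly: pattern must be 12 non-negative weights ",
         "summing to 1")
  amounts <- cbind(c_above = annual$c_above * pattern,
                   c_below = annual$c_below * pattern,
                   c_rhizo = annual$c_rhizo * pattern)
  ndf <- if (is.null(ndf_by_month)) rep(ndf_above, 12) else ndf_by_month
  f_dpm <- f_rpm <- matrix(0, 12, 3,
                           dimnames = list(NULL,
                                           c("c_above", "c_below", "c_rhizo")))
  for (m in 1:12) {
    q <- component_quality(ndf[m], lignin_offset_below)
    f_dpm[m, ] <- c(q$above["f_dpm"], q$below["f_dpm"], q$rhizo["f_dpm"])
    f_rpm[m, ] <- c(q$above["f_rpm"], q$below["f_rpm"], q$rhizo["f_rpm"])
  }
  structure(list(amounts = amounts, f_dpm = f_dpm, f_rpm = f_rpm),
            class = "monthly_c_input")
}

#' Monthly plant inputs for a residue specification
#'
#' Convenience wrapper chaining [annual_components()] and
#' [distribute_monthly()].
#'
#' @param spec a [plant_residue_spec()]
#' @return a `monthly_c_input`
#' @export
plant_monthly_inputs <- function(spec) {
  distribute_monthly(annual_components(spec),
                     pattern = spec$monthly_pattern,
                     ndf_above = spec$ndf_above,
                     ndf_by_month = spec$ndf_by_month,
                     lignin_offset_below = spec$lignin_offset_below)
}
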