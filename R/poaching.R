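#' Poaching (livestock trampling) damage parameters
#'
#' Poaching — hoof damage to the sward on wet soil — reduces pasture
#' production and hence the month's plant carbon input. The trigger is
#' grazing on near-saturated soil (signed SMD at or below the threshold,
#' default -10 mm); severity grows linearly with stocking density up to a
#' cap. Damage is month-local: swards recover quickly, so no carry-over.
#'
#' @param smd_threshold signed SMD (mm) at or below which soil is prone to
#'   poaching; must be <= 0 (default -10)
#' @param damage_per_lsu fractional input reduction per LSU ha\eqn{^{-1}}
#'   (default 0.10)
#' @param max_reduction cap on the fractional reduction, in \[0, 1\]
#'   (default 0.5)
#' @return an object of class `poaching_params`
#' @export
poaching_params <- function(smd_threshold = -10, damage_per_lsu = 0.10,
                            max_reduction = 0.5) {
  if (!is.finite(smd_threshold) || smd_threshold > 0)
    stop("poaching_params: smd_threshold must be <= 0 mm")
  if (!is.finite(damage_per_lsu) || damage_per_lsu < 0)
    stop("poaching_params: damage_per_lsu must be >= 0")
  if (!is.finite(max_reduction) || max_reduction < 0 || max_reduction > 1)
    stop("poaching_params: max_reduction must be in [0, 1]")
  structure(list(smd_threshold = smd_threshold,
                 damage_per_lsu = damage_per_lsu,
                 max_reduction = max_reduction),
            class = "poaching_params")
}

#' Does poaching occur this month?
#'
#' TRUE iff animals graze this month and the soil is at or wetter than the
#' poaching threshold.
#'
#' @param smd signed soil moisture deficit, mm
#' @param grazing_this_month logical
#' @param params a [poaching_params()]
#' @return logical
#' @export
poaching_active <- function(smd, grazing_this_month,
                            params = poaching_params()) {
  isTRUE(as.logical(grazing_this_month)) && smd <= params$smd_threshold
}

#' Fractional plant-input reduction from stocking density
#'
#' min(max_reduction, damage_per_lsu x stocking rate): zero without
#' animals, non-decreasing, capped.
#'
#' @param stocking_rate LSU ha\eqn{^{-1}}, >= 0
#' @param params a [poaching_params()]
#' @return fraction in \[0, 1\]
#' @export
input_reduction <- function(stocking_rate, params = poaching_params()) {
  if (!is.finite(stocking_rate) || stocking_rate < 0)
    stop("input_reduction: stocking_rate must be >= 0")
  min(params$max_reduction, params$damage_per_lsu * stocking_rate)
}

#' Apply poaching damage to a month's plant inputs
#'
#' When active, every plant component of the month (above-ground,
#' below-ground, rhizodeposition) is scaled by (1 - reduction). Applied
#' amendments (EOM) are untouched. Inactive months pass through unchanged.
#'
#' @param month_amounts named numeric of the month's plant C components
#'   (any names), Mg C ha\eqn{^{-1}}
#' @param active logical from [poaching_active()]
#' @param reduction fraction in \[0, 1\] from [input_reduction()]
#' @return the (possibly scaled) amounts
#' @export
apply_poaching <- function(month_amounts, active, reduction) {
  if (!is.finite(reduction) || reduction < 0 || reduction > 1)
    stop("apply_poaching: reduction must be in [0, 1]")
  if (isTRUE(active)) month_amounts * (1 - reduction) else month_amounts
}
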