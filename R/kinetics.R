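#' Five-pool carbon state
#'
#' Constructs the carbon state tracked by the monthly decomposition engine:
#' decomposable plant material (DPM), resistant plant material (RPM),
#' microbial biomass (BIO), humified organic matter (HUM) and inert organic
#' matter (IOM), all in Mg C ha\eqn{^{-1}}. A running total of respired
#' CO\eqn{_2} is carried for mass-balance audits.
#'
#' IOM never decomposes: it is fixed at initialisation and carried through
#' every step unchanged.
#'
#' @param dpm,rpm,bio,hum,iom pool sizes, Mg C ha\eqn{^{-1}}, all >= 0
#' @param cumulative_co2 respired C accumulated so far, Mg C ha\eqn{^{-1}}
#' @return an object of class `carbon_state` (a named list)
#' @seealso [step_month()], [init_pools()]
#' @export
carbon_state <- function(dpm = 0, rpm = 0, bio = 0, hum = 0, iom = 0,
                         cumulative_co2 = 0) {
  dpm <- unname(dpm); rpm <- unname(rpm); bio <- unname(bio)
  hum <- unname(hum); iom <- unname(iom)
  cumulative_co2 <- unname(cumulative_co2)
  vals <- c(dpm = dpm, rpm = rpm, bio = bio, hum = hum, iom = iom)
  if (any(!is.finite(vals)) || !is.finite(cumulative_co2))
    stop("carbon_state: all pools must be finite numbers")
  if (any(vals < 0))
    stop("carbon_state: negative pool size: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  structure(list(dpm = dpm, rpm = rpm, bio = bio, hum = hum, iom = iom,
                 cumulative_co2 = cumulative_co2),
            class = "carbon_state")
}

#' @export
print.carbon_state <- function(x, ...) {
  cat("Carbon pools (Mg C/ha):\n")
  print(round(c(DPM = x$dpm, RPM = x$rpm, BIO = x$bio, HUM = x$hum,
                IOM = x$iom, total = total_soc(x)), 3))
  invisible(x)
}

#' Total soil organic carbon of a state
#'
#' @param state a [carbon_state()]
#' @return total SOC (all five pools), Mg C ha\eqn{^{-1}}
#' @export
total_soc <- function(state) {
  state$dpm + state$rpm + state$bio + state$hum + state$iom
}

#' Decomposition rate constants
#'
#' RothC-26.3 first-order rate constants (yr\eqn{^{-1}}) for the four active
#' pools. The defaults are the reference values 10 (DPM), 0.3 (RPM),
#' 0.66 (BIO) and 0.02 (HUM).
#'
#' @param k_dpm,k_rpm,k_bio,k_hum turnover rate constants, yr\eqn{^{-1}}
#' @return an object of class `decay_constants`
#' @export
decay_constants <- function(k_dpm = 10, k_rpm = 0.3, k_bio = 0.66,
                            k_hum = 0.02) {
  k <- c(k_dpm = k_dpm, k_rpm = k_rpm, k_bio = k_bio, k_hum = k_hum)
  if (any(!is.finite(k)) || any(k <= 0))
    stop("decay_constants: all rate constants must be positive")
  if (!(k_dpm > k_bio && k_bio > k_rpm && k_rpm > k_hum))
    stop("decay_constants: expected ordering k_dpm > k_bio > k_rpm > k_hum")
  structure(as.list(k), class = "decay_constants")
}

#' Temperature rate-modifying factor
#'
#' RothC-26.3 factor `a`: 47.91 / (1 + exp(106.06 / (T + 18.27))) for monthly
#' mean air temperature T above -18.27 degC; zero at or below that cutoff
#' (decomposition halted by frost).
#'
#' @param t_mean monthly mean air temperature, degC (vectorised)
#' @return dimensionless factor >= 0, strictly increasing above the cutoff
#' @export
rate_modifier_temperature <- function(t_mean) {
  if (any(!is.finite(t_mean)))
    stop("rate_modifier_temperature: t_mean must be finite")
  ifelse(t_mean <= -18.27, 0,
         47.91 / (1 + exp(106.06 / (t_mean + 18.27))))
}

#' Plant-cover rate-modifying factor
#'
#' RothC-26.3 factor `c`: decomposition is retarded under a growing crop
#' (0.6) relative to bare soil (1.0).
#'
#' @param vegetated logical; is the soil covered by growing vegetation?
#' @return 0.6 if vegetated, 1.0 if bare (vectorised)
#' @export
rate_modifier_cover <- function(vegetated) {
  ifelse(as.logical(vegetated), 0.6, 1.0)
}

#' Clay-dependent partition of decomposed carbon
#'
#' Splits the carbon leaving the active pools in a month between respired
#' CO2 and the BIO and HUM pools. The CO2/(BIO+HUM) ratio is
#' x = 1.67 (1.85 + 1.60 exp(-0.0786 clay)); of the retained carbon 46%
#' goes to BIO and 54% to HUM. The three shares sum to the decomposed
#' amount exactly.
#'
#' @param decomposed_c carbon decomposed this month, Mg C ha\eqn{^{-1}}, >= 0
#' @param clay soil clay content, percent (0-100)
#' @return named list with `co2`, `bio`, `hum` (Mg C ha\eqn{^{-1}})
#' @export
partition_decomposed <- function(decomposed_c, clay) {
  if (!is.finite(decomposed_c) || decomposed_c < 0)
    stop("partition_decomposed: decomposed_c must be >= 0")
  if (!is.finite(clay) || clay < 0 || clay > 100)
    stop("partition_decomposed: clay must be in [0, 100]")
  x <- 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay))
  retained <- decomposed_c / (1 + x)
  list(co2 = decomposed_c - retained,
       bio = 0.46 * retained,
       hum = 0.54 * retained)
}

#' One monthly decomposition step
#'
#' Advances a [carbon_state()] by one month. Each active pool P first decays
#' to P exp(-k_P a b c / 12); the decomposed carbon is partitioned into
#' CO2/BIO/HUM by [partition_decomposed()]; fresh inputs are then credited
#' to their entry pools. Crediting inputs after decay of the pre-existing
#' stock makes the mass balance unambiguous: delta SOC over the step equals
#' total input minus CO2 respired.
#'
#' @param state a [carbon_state()]
#' @param modifiers named list/vector with elements `a` (temperature),
#'   `b` (moisture, in \[0.2, 1\]) and `c` (cover, 0.6 or 1.0)
#' @param inputs named list of entry-pool additions for the month, Mg C
#'   ha\eqn{^{-1}}: `dpm`, `rpm`, `hum` (missing elements default to 0)
#' @param clay soil clay content, percent
#' @param constants a [decay_constants()]
#' @return the updated `carbon_state`
#' @export
step_month <- function(state, modifiers, inputs = list(), clay,
                       constants = decay_constants()) {
  a <- modifiers$a; b <- modifiers$b; cc <- modifiers$c
  if (any(!is.finite(c(a, b, cc))) || a < 0)
    stop("step_month: invalid rate modifiers")
  if (b < 0.2 - 1e-12 || b > 1 + 1e-12)
    stop("step_month: moisture factor b outside [0.2, 1]")
  abc <- a * b * cc

  pools <- c(dpm = state$dpm, rpm = state$rpm, bio = state$bio,
             hum = state$hum)
  k <- c(constants$k_dpm, constants$k_rpm, constants$k_bio, constants$k_hum)
  remaining <- pools * exp(-k * abc / 12)
  decomposed <- sum(pools - remaining)

  part <- partition_decomposed(decomposed, clay)

  add <- function(nm) if (is.null(inputs[[nm]])) 0 else inputs[[nm]]
  carbon_state(
    dpm = remaining[["dpm"]] + add("dpm"),
    rpm = remaining[["rpm"]] + add("rpm"),
    bio = remaining[["bio"]] + part$bio,
    hum = remaining[["hum"]] + part$hum + add("hum"),
    iom = state$iom,
    cumulative_co2 = state$cumulative_co2 + part$co2
  )
}

#' Default plant-material entry split
#'
#' The reference model routes lumped plant input to DPM and RPM with a
#' DPM:RPM ratio of 1.44, i.e. a 59/41 split. Used whenever the
#' three-component plant residue modification is switched off.
#'
#' @param ratio DPM:RPM ratio (default 1.44)
#' @return named vector `c(f_dpm, f_rpm)` summing to 1
#' @export
default_plant_split <- function(ratio = 1.44) {
  if (!is.finite(ratio) || ratio < 0)
    stop("default_plant_split: ratio must be >= 0")
  f_dpm <- ratio / (1 + ratio)
  c(f_dpm = f_dpm, f_rpm = 1 - f_dpm)
}
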