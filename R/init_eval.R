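#' Inert organic matter from total stock (Falloon equation)
#'
#' IOM = 0.049 TOC^1.139, both in Mg C ha\eqn{^{-1}}. The standard way of
#' fixing the inert pool from a measured stock when radiocarbon data are
#' unavailable.
#'
#' @param toc total soil organic carbon, Mg C ha\eqn{^{-1}}, >= 0
#' @return IOM, Mg C ha\eqn{^{-1}} (vectorised)
#' @export
iom_falloon <- function(toc) {
  if (any(!is.finite(toc)) || any(toc < 0))
    stop("iom_falloon: toc must be >= 0")
  0.049 * toc^1.139
}

#' Initialise the five pools from a measured SOC stock
#'
#' `method = "pedotransfer"` (default): IOM from [iom_falloon()]; RPM, HUM
#' and BIO from the Weihermueller et al. (2013) SOC/clay pedotransfer
#' forms, with DPM as the residual so the pools sum to `soc` exactly:
#' \itemize{
#'   \item RPM = (0.1847 SOC + 0.1555) (clay + 1.2750)^-0.1158
#'   \item HUM = (0.7148 SOC + 0.5069) (clay + 0.3421)^0.0184
#'   \item BIO = (0.0140 SOC + 0.0075) (clay + 8.8473)^0.0567
#' }
#' `method = "spinup"`: run the supplied scenario function to
#' quasi-equilibrium under repeating forcing, then rescale the active
#' pools so the total matches `soc` (IOM still from the Falloon equation).
#'
#' @param soc measured total SOC, Mg C ha\eqn{^{-1}}
#' @param clay clay content, percent
#' @param method `"pedotransfer"` or `"spinup"`
#' @param spinup_run for `"spinup"`: a function of an initial
#'   [carbon_state()] returning the state after one forcing cycle
#' @param spinup_tol relative SOC change per cycle below which the spinup
#'   is considered at equilibrium
#' @param spinup_max_cycles cap on forcing cycles
#' @return a [carbon_state()] whose pools sum to `soc` exactly
#' @references Weihermueller L., Graf A., Herbst M., Vereecken H. (2013)
#'   Simple pedotransfer functions to initialize reactive carbon pools of
#'   the RothC model. Eur. J. Soil Sci. 64:567-575.
#' @export
init_pools <- function(soc, clay, method = c("pedotransfer", "spinup"),
                       spinup_run = NULL, spinup_tol = 1e-6,
                       spinup_max_cycles = 2000) {
  method <- match.arg(method)
  if (!is.finite(soc) || soc <= 0)
    stop("init_pools: soc must be > 0")
  iom <- iom_falloon(soc)
  if (iom >= soc)
    stop("init_pools: Falloon IOM (", round(iom, 2),
         ") is not below the stock; soc too small")
  if (method == "pedotransfer") {
    rpm <- (0.1847 * soc + 0.1555) * (clay + 1.2750)^(-0.1158)
    hum <- (0.7148 * soc + 0.5069) * (clay + 0.3421)^(0.0184)
    bio <- (0.0140 * soc + 0.0075) * (clay + 8.8473)^(0.0567)
    dpm <- soc - iom - rpm - hum - bio
    if (dpm < -0.05 * soc)
      stop("init_pools: residual DPM strongly negative (", round(dpm, 3),
           "); pedotransfer inconsistent with this soc/clay")
    if (dpm < 0) {
      # the fitted forms can overshoot the stock by a fraction of a
      # percent at high SOC; close the balance on the estimated pools
      dpm <- 0
      scale <- (soc - iom) / (rpm + hum + bio)
      rpm <- rpm * scale; hum <- hum * scale; bio <- bio * scale
    }
    carbon_state(dpm = dpm, rpm = rpm, bio = bio, hum = hum, iom = iom)
  } else {
    if (!is.function(spinup_run))
      stop("init_pools: spinup needs a `spinup_run` function")
    st <- carbon_state(dpm = 0.1, rpm = 1, bio = 0.5, hum = 5, iom = iom)
    for (i in seq_len(spinup_max_cycles)) {
      nxt <- spinup_run(st)
      if (abs(total_soc(nxt) - total_soc(st)) <=
          spinup_tol * total_soc(st)) { st <- nxt; break }
      st <- nxt
    }
    active <- total_soc(st) - st$iom
    scale <- (soc - iom) / active
    carbon_state(dpm = st$dpm * scale, rpm = st$rpm * scale,
                 bio = st$bio * scale, hum = st$hum * scale, iom = iom)
  }
}

#' Evaluate simulated against observed SOC stocks
#'
#' Pairs the two series by year and computes the mean difference
#' BIAS = mean(sim - obs) (negative = underestimation), the root mean
#' square error both absolute and as percent of the observed mean, and
#' the Nash-Sutcliffe model efficiency
#' EF = 1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2) (1 = perfect;
#' needs at least two observations).
#'
#' @param observed data.frame with columns `year`, `soc`
#' @param simulated data.frame with columns `year`, `soc`
#' @return object of class `soc_evaluation`: `bias`, `rmse_abs`,
#'   `rmse_pct`, `ef` (NA when n < 2), `n`
#' @export
evaluate_soc <- function(observed, simulated) {
  for (d in list(observed, simulated))
    if (!all(c("year", "soc") %in% names(d)))
      stop("evaluate_soc: need columns `year` and `soc`")
  m <- merge(observed[, c("year", "soc")], simulated[, c("year", "soc")],
             by = "year", suffixes = c("_obs", "_sim"))
  if (nrow(m) < 1)
    stop("evaluate_soc: no overlapping years")
  err <- m$soc_sim - m$soc_obs
  n <- nrow(m)
  ef <- if (n >= 2) {
    ss <- sum((m$soc_obs - mean(m$soc_obs))^2)
    if (ss == 0) NA_real_ else 1 - sum(err^2) / ss
  } else NA_real_
  structure(list(bias = mean(err),
                 rmse_abs = sqrt(mean(err^2)),
                 rmse_pct = 100 * sqrt(mean(err^2)) / mean(m$soc_obs),
                 ef = ef, n = n),
            class = "soc_evaluation")
}

#' @export
print.soc_evaluation <- function(x, ...) {
  cat(sprintf("SOC evaluation over %d paired years\n", x$n))
  cat(sprintf("  BIAS (sim - obs): %8.3f Mg C/ha\n", x$bias))
  cat(sprintf("  RMSE:             %8.3f Mg C/ha (%.2f%% of obs mean)\n",
              x$rmse_abs, x$rmse_pct))
  if (!is.na(x$ef)) cat(sprintf("  EF:               %8.3f\n", x$ef))
  invisible(x)
}

#' Sensitivity index of a set of model outputs
#'
#' (max - min) / max over the outputs of a one-at-a-time parameter sweep.
#' Scale-invariant and in \[0, 1) for positive outputs.
#'
#' @param outputs numeric vector of final SOC values, all > 0
#' @param as_percent return the index x 100 (default TRUE)
#' @return dimensionless index (or percent)
#' @export
sensitivity_index <- function(outputs, as_percent = TRUE) {
  if (length(outputs) == 0 || any(!is.finite(outputs)) || any(outputs <= 0))
    stop("sensitivity_index: outputs must be non-empty and > 0")
  idx <- (max(outputs) - min(outputs)) / max(outputs)
  if (as_percent) 100 * idx else idx
}
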