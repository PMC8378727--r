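#' Feature flags of the cumulative version ladder
#'
#' The four grassland modifications are layered cumulatively on the
#' reference model: `RothC_0` (none), `RothC_1` (+ ruminant excreta
#' quality), `RothC_2` (+ three-component plant residues with quality),
#' `RothC_3` (+ soil moisture extended to saturation), `RothC_4`
#' (+ poaching). Arbitrary flag combinations are allowed through
#' [rothc_config()]'s `flags` argument (expert mode).
#'
#' @param version one of `"RothC_0"` ... `"RothC_4"`
#' @return named logical vector with elements `excreta_quality`,
#'   `plant_residue`, `moisture_saturation`, `poaching`
#' @export
rothc_version_flags <- function(version) {
  versions <- paste0("RothC_", 0:4)
  i <- match(version, versions)
  if (is.na(i)) stop("unknown version: ", version,
                     " (expected one of ", paste(versions, collapse = ", "), ")")
  n <- i - 1
  c(excreta_quality = n >= 1, plant_residue = n >= 2,
    moisture_saturation = n >= 3, poaching = n >= 4)
}

#' Scenario configuration
#'
#' Bundles site, soil, management and modification flags for
#' [run_rothc()].
#'
#' @param version preset name passed to [rothc_version_flags()]; ignored
#'   when `flags` is given explicitly
#' @param flags optional named logical vector overriding the preset
#'   (expert mode: any combination)
#' @param clay,sand,silt soil texture, percent (must sum to ~100)
#' @param depth simulated topsoil depth, cm (20 or 30 in typical use)
#' @param initial_soc measured initial SOC stock, Mg C ha\eqn{^{-1}}
#' @param om topsoil organic matter percent for the water pedotransfer
#' @param plant a [plant_residue_spec()]
#' @param eom_applications list of EOM applications (see
#'   [eom_monthly_inputs()]); month numbers are within-year (1-12) and
#'   repeat every simulated year
#' @param grazing_months integer months (1-12) with grazing animals
#' @param stocking_rate LSU ha\eqn{^{-1}} during grazing months
#' @param vegetated_months integer months with growing vegetation
#'   (default all 12: permanent grassland)
#' @param poaching a [poaching_params()]
#' @param evap_factor 0.75 for open-pan evaporation input, 1.0 for PET
#' @param pin_moisture_b optional constant overriding the moisture factor
#'   `b` (used by sensitivity sweeps); NULL for normal operation
#' @return an object of class `rothc_config`
#' @export
rothc_config <- function(version = "RothC_4", flags = NULL,
                         clay, sand, silt = 100 - clay - sand,
                         depth = 20, initial_soc, om = 2.5,
                         plant, eom_applications = list(),
                         grazing_months = integer(0), stocking_rate = 0,
                         vegetated_months = 1:12,
                         poaching = poaching_params(),
                         evap_factor = 0.75, pin_moisture_b = NULL) {
  if (is.null(flags)) flags <- rothc_version_flags(version)
  needed <- c("excreta_quality", "plant_residue", "moisture_saturation",
              "poaching")
  if (!all(needed %in% names(flags)))
    stop("rothc_config: flags must name ", paste(needed, collapse = ", "))
  flags <- as.logical(flags[needed]); names(flags) <- needed
  if (!inherits(plant, "plant_residue_spec"))
    stop("rothc_config: `plant` must be a plant_residue_spec")
  if (length(grazing_months) == 0 && stocking_rate > 0)
    stop("rothc_config: stocking_rate > 0 requires grazing months")
  if (length(grazing_months) > 0 && !all(grazing_months %in% 1:12))
    stop("rothc_config: grazing_months must be in 1..12")
  if (flags[["poaching"]] && length(grazing_months) == 0)
    message("rothc_config: poaching enabled but no grazing months; ",
            "the modification is inert")
  if (!is.null(pin_moisture_b) &&
      (pin_moisture_b < 0.2 || pin_moisture_b > 1))
    stop("rothc_config: pin_moisture_b must be in [0.2, 1]")
  structure(list(version = version, flags = flags,
                 clay = clay, sand = sand, silt = silt, depth = depth,
                 initial_soc = initial_soc, om = om, plant = plant,
                 eom_applications = eom_applications,
                 grazing_months = as.integer(grazing_months),
                 stocking_rate = stocking_rate,
                 vegetated_months = as.integer(vegetated_months),
                 poaching = poaching, evap_factor = evap_factor,
                 pin_moisture_b = pin_moisture_b),
            class = "rothc_config")
}

#' @export
print.rothc_config <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat("RothC scenario configuration (", x$version, ")\n", sep = "")
  cat("  modifications on:", if (length(on)) paste(on, collapse = ", ")
      else "none (reference model)", "\n")
  cat(sprintf("  soil: clay %.0f%%, sand %.0f%%, silt %.0f%%, depth %.0f cm\n",
              x$clay, x$sand, x$silt, x$depth))
  cat(sprintf("  initial SOC: %.1f Mg C/ha\n", x$initial_soc))
  cat(sprintf("  management: %s, N input %.0f kg N/ha/yr",
              x$plant$management, x$plant$n_input))
  if (length(x$grazing_months))
    cat(sprintf(", grazing months %s at %.2f LSU/ha",
                paste(x$grazing_months, collapse = ","), x$stocking_rate))
  cat("\n")
  invisible(x)
}

# Assemble per-month plant input amounts and qualities for one calendar
# year, honouring the plant_residue flag (legacy path: above-ground
# residue only, lumped at the default 1.44 DPM:RPM split).
.plant_schedule <- function(config) {
  spec <- config$plant
  if (config$flags[["plant_residue"]]) {
    plant_monthly_inputs(spec)
  } else {
    ann <- annual_components(spec)
    pattern <- spec$monthly_pattern
    split <- default_plant_split()
    amounts <- cbind(c_above = ann$c_above * pattern,
                     c_below = 0 * pattern, c_rhizo = 0 * pattern)
    f_dpm <- matrix(split[["f_dpm"]], 12, 3,
                    dimnames = list(NULL, colnames(amounts)))
    f_rpm <- 1 - f_dpm
    structure(list(amounts = amounts, f_dpm = f_dpm, f_rpm = f_rpm),
              class = "monthly_c_input")
  }
}

# EOM schedule honouring the excreta_quality flag (off: everything gets
# the reference farmyard-manure split).
.eom_schedule <- function(config) {
  apps <- config$eom_applications
  if (length(apps) == 0)
    return(matrix(0, 12, 3, dimnames = list(NULL, c("dpm", "rpm", "hum"))))
  if (config$flags[["excreta_quality"]]) {
    eom_monthly_inputs(apps)
  } else {
    apps <- lapply(apps, function(a) {
      a$quality <- NULL; a$partition <- fym_partition(); a
    })
    eom_monthly_inputs(apps)
  }
}

#' Run a scenario over a monthly weather series
#'
#' The monthly loop: update the soil moisture deficit, compute the three
#' rate-modifying factors (extended wet-side moisture decline only under
#' the `moisture_saturation` flag), assemble plant and EOM inputs per the
#' active flags, damp plant inputs by poaching where triggered, and take
#' one decomposition step. Deterministic given config and weather.
#'
#' @param config a [rothc_config()]
#' @param weather data.frame with columns `year`, `month`, `tmean_c`,
#'   `precip_mm`, `evap_mm`; months must be contiguous and complete
#' @param initial_state optional [carbon_state()]; default
#'   [init_pools()] from `initial_soc` and clay
#' @param initial_smd starting signed SMD, mm (default 0 = field capacity)
#' @return an object of class `rothc_run`: `monthly` (data.frame of
#'   pools, SOC, CO2, SMD, modifiers and poaching flags), `annual`
#'   (December SOC per year), `mass_balance`, `config`
#' @export
run_rothc <- function(config, weather, initial_state = NULL,
                      initial_smd = 0) {
  stopifnot(inherits(config, "rothc_config"))
  need <- c("year", "month", "tmean_c", "precip_mm", "evap_mm")
  if (!all(need %in% names(weather)))
    stop("run_rothc: weather needs columns ", paste(need, collapse = ", "))
  weather <- weather[order(weather$year, weather$month), , drop = FALSE]
  span <- (weather$year - weather$year[1]) * 12 + weather$month
  if (any(diff(span) != 1)) {
    gap <- which(diff(span) != 1)[1]
    stop("run_rothc: weather series has a gap after year ",
         weather$year[gap], " month ", weather$month[gap])
  }

  bounds <- pedotransfer_water(config$clay, config$sand, config$silt,
                               depth = config$depth, om = config$om)
  state <- if (is.null(initial_state))
    init_pools(config$initial_soc, config$clay) else initial_state
  flags <- config$flags
  plant <- .plant_schedule(config)
  eom <- .eom_schedule(config)
  grazing <- 1:12 %in% config$grazing_months
  vegetated <- 1:12 %in% config$vegetated_months
  reduction <- input_reduction(config$stocking_rate, config$poaching)

  n <- nrow(weather)
  soc0 <- total_soc(state)
  smd <- initial_smd
  total_in <- 0
  rows <- vector("list", n)

  for (i in seq_len(n)) {
    m <- weather$month[i]
    smd <- update_smd(smd, weather$precip_mm[i], weather$evap_mm[i],
                      vegetated[m], bounds,
                      allow_saturation = flags[["moisture_saturation"]],
                      evap_factor = config$evap_factor)
    a <- rate_modifier_temperature(weather$tmean_c[i])
    b <- if (!is.null(config$pin_moisture_b)) config$pin_moisture_b
         else rate_modifier_moisture(smd, bounds,
                                     extended = flags[["moisture_saturation"]],
                                     vegetated = vegetated[m])
    cc <- rate_modifier_cover(vegetated[m])

    active <- flags[["poaching"]] &&
      poaching_active(smd, grazing[m], config$poaching)
    amounts <- apply_poaching(plant$amounts[m, ], active, reduction)
    dpm_in <- sum(amounts * plant$f_dpm[m, ]) + eom[m, "dpm"]
    rpm_in <- sum(amounts * plant$f_rpm[m, ]) + eom[m, "rpm"]
    hum_in <- eom[m, "hum"]
    month_in <- dpm_in + rpm_in + hum_in
    total_in <- total_in + month_in

    co2_before <- state$cumulative_co2
    state <- step_month(state, list(a = a, b = b, c = cc),
                        list(dpm = dpm_in, rpm = rpm_in, hum = hum_in),
                        clay = config$clay)
    rows[[i]] <- data.frame(
      year = as.integer(weather$year[i]), month = as.integer(m),
      dpm = state$dpm, rpm = state$rpm, bio = state$bio, hum = state$hum,
      iom = state$iom, soc_total = total_soc(state),
      co2_month = state$cumulative_co2 - co2_before,
      c_input = month_in, smd_mm = smd,
      mod_a = a, mod_b = b, mod_c = cc,
      poaching_flag = active
    )
  }
  monthly <- do.call(rbind, rows)
  annual <- monthly[monthly$month == 12, c("year", "soc_total")]
  names(annual) <- c("year", "soc")
  rownames(annual) <- NULL

  delta <- total_soc(state) - soc0
  co2 <- state$cumulative_co2
  throughput <- max(total_in + co2, soc0)
  structure(list(monthly = monthly, annual = annual,
                 mass_balance = list(total_inputs = total_in,
                                     total_co2 = co2, delta_soc = delta,
                                     rel_error =
                                       abs(delta - (total_in - co2)) /
                                       throughput),
                 final_state = state, config = config),
            class = "rothc_run")
}

#' @export
print.rothc_run <- function(x, ...) {
  nyr <- nrow(x$annual)
  cat("RothC run (", x$config$version, "): ", nyr, " years, ",
      nrow(x$monthly), " monthly steps\n", sep = "")
  cat(sprintf("  SOC: %.2f -> %.2f Mg C/ha\n",
              x$monthly$soc_total[1] - x$monthly$c_input[1] +
                x$monthly$co2_month[1],
              x$annual$soc[nyr]))
  cat(sprintf("  total C input %.2f, total CO2 %.2f Mg C/ha\n",
              x$mass_balance$total_inputs, x$mass_balance$total_co2))
  invisible(x)
}

#' @export
summary.rothc_run <- function(object, ...) {
  x <- object
  cat("Annual December SOC stocks (Mg C/ha):\n")
  print(transform(x$annual, soc = round(soc, 2)), row.names = FALSE)
  cat(sprintf("\nMass balance residual: %.2e (relative)\n",
              x$mass_balance$rel_error))
  np <- sum(x$monthly$poaching_flag)
  cat(sprintf("Poaching-active months: %d of %d\n", np, nrow(x$monthly)))
  invisible(x)
}

#' @export
as.data.frame.rothc_run <- function(x, ...) x$monthly

#' @export
plot.rothc_run <- function(x, ..., annotate_poaching = TRUE) {
  t <- x$monthly$year + (x$monthly$month - 0.5) / 12
  plot(t, x$monthly$soc_total, type = "l",
       xlab = "Year", ylab = "SOC (Mg C/ha)",
       main = paste("Simulated SOC,", x$config$version), ...)
  if (annotate_poaching && any(x$monthly$poaching_flag))
    points(t[x$monthly$poaching_flag],
           x$monthly$soc_total[x$monthly$poaching_flag],
           pch = 4, col = "red3")
  invisible(x)
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs the full scenario at each grid point of one swept input,
#' holding everything else fixed, and summarises the final SOC values by
#' [sensitivity_index()]. Swept inputs and their admissible domains:
#' `"ndf"` (above-ground NDF, 30-70%), `"lignin"` (EOM lignin, 9-28% VS),
#' `"moisture_factor"` (the rate-modifying factor `b` pinned to a
#' constant, 0.2-1).
#'
#' @param config a [rothc_config()]
#' @param weather weather series as for [run_rothc()]
#' @param parameter `"ndf"`, `"lignin"` or `"moisture_factor"`
#' @param interval numeric length-2 `c(min, max)` within the domain
#' @param n_points grid size (default 2: the endpoints)
#' @return object of class `sensitivity_result`: `grid`, `outputs`
#'   (final SOC per grid point), `index` (percent)
#' @export
sweep_sensitivity <- function(config, weather,
                              parameter = c("ndf", "lignin",
                                            "moisture_factor"),
                              interval, n_points = 2) {
  parameter <- match.arg(parameter)
  domain <- switch(parameter, ndf = c(30, 70), lignin = c(9, 28),
                   moisture_factor = c(0.2, 1))
  if (length(interval) != 2 || interval[1] > interval[2] ||
      interval[1] < domain[1] - 1e-9 || interval[2] > domain[2] + 1e-9)
    stop("sweep_sensitivity: interval must lie within [",
         domain[1], ", ", domain[2], "] for ", parameter)
  grid <- seq(interval[1], interval[2], length.out = max(2, n_points))
  if (interval[1] == interval[2]) grid <- rep(interval[1], 2)

  outputs <- vapply(grid, function(v) {
    cfg <- config
    if (parameter == "ndf") {
      cfg$plant$ndf_above <- v
      cfg$plant$ndf_by_month <- NULL
    } else if (parameter == "lignin") {
      cfg$eom_applications <- lapply(cfg$eom_applications, function(a) {
        rest <- 100 - v
        # keep the default holocellulose:solubles proportion of the rest
        a$partition <- NULL
        a$quality <- eom_quality(lignin = v, holocellulose = rest * 45 / 81.5,
                                 solubles = rest * 36.5 / 81.5,
                                 label = sprintf("sweep lignin %.1f%%", v))
        a
      })
    } else {
      cfg$pin_moisture_b <- v
    }
    run <- run_rothc(cfg, weather)
    run$annual$soc[nrow(run$annual)]
  }, numeric(1))

  structure(list(parameter = parameter, grid = grid, outputs = outputs,
                 index = sensitivity_index(outputs)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity sweep of %s over [%g, %g] (%d points)\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  final SOC: min %.1f, max %.1f Mg C/ha\n",
              min(x$outputs), max(x$outputs)))
  cat(sprintf("  sensitivity index: %.1f%%\n", x$index))
  invisible(x)
}
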