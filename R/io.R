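# File interfaces: weather and observation CSVs, results round-trip,
# structured scenario configuration (YAML or JSON).

#' Load a monthly weather series from CSV
#'
#' Expected columns: `year`, `month`, `tmean_c`, `precip_mm`, `evap_mm`.
#' The series must be complete and contiguous; gaps are reported by
#' position.
#'
#' @param path CSV file path
#' @return validated data.frame
#' @export
load_weather <- function(path) {
  w <- utils::read.csv(path)
  need <- c("year", "month", "tmean_c", "precip_mm", "evap_mm")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("load_weather: ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!w$month %in% 1:12))
    stop("load_weather: month values must be integers 1..12")
  w <- w[order(w$year, w$month), ]
  span <- (w$year - w$year[1]) * 12 + w$month
  if (any(diff(span) != 1)) {
    gap <- which(diff(span) != 1)[1]
    stop("load_weather: gap in series after year ", w$year[gap],
         " month ", w$month[gap])
  }
  if (any(w$precip_mm < 0) || any(w$evap_mm < 0))
    stop("load_weather: precip_mm and evap_mm must be >= 0")
  w
}

#' Load observed annual SOC stocks from CSV
#'
#' Expected columns: `year`, `soc` (Mg C ha\eqn{^{-1}}); an optional `sd`
#' column is carried through.
#'
#' @param path CSV file path
#' @return data.frame
#' @export
load_observations <- function(path) {
  o <- utils::read.csv(path)
  if (!all(c("year", "soc") %in% names(o)))
    stop("load_observations: need columns `year` and `soc`")
  if (any(o$soc < 0)) stop("load_observations: negative SOC stock")
  o[order(o$year), ]
}

#' Write a simulation result to CSV (round-trip exact)
#'
#' Writes the monthly series of a [run_rothc()] result with 17
#' significant digits so that [read_results()] reproduces the numbers
#' bit-exactly.
#'
#' @param run a `rothc_run`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_results <- function(run, path) {
  stopifnot(inherits(run, "rothc_run"))
  df <- run$monthly
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path
#' @return data.frame matching the run's monthly series
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path)
  df$poaching_flag <- as.logical(df$poaching_flag)
  df
}

#' Load a scenario configuration from a structured file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON (`.json`). Schema (all carbon in
#' Mg C ha\eqn{^{-1}}, water in mm, months 1-12):
#' \preformatted{
#' version: RothC_4            # or flags: {excreta_quality: true, ...}
#' site: {clay, sand, silt, depth_cm, initial_soc, om}
#' plant: {management, above_ground_biomass, n_input, ndf_above,
#'         rs_ratio, monthly_pattern, ndf_by_month}   # last three optional
#' management: {grazing_months, stocking_rate, vegetated_months}
#' eom:                        # optional list of applications
#'   - {month, c_amount, lignin, holocellulose, solubles}
#' poaching: {smd_threshold_mm, damage_per_lsu, max_reduction}
#' evap_factor: 0.75
#' }
#'
#' @param path configuration file path
#' @return a [rothc_config()]
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("load_config: package `yaml` required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("load_config: package `jsonlite` required for JSON configs")
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else stop("load_config: unsupported extension `.", ext, "`")

  site <- raw$site
  if (is.null(site$clay) || is.null(site$initial_soc))
    stop("load_config: site block must give at least clay and initial_soc")
  pl <- raw$plant
  if (is.null(pl))
    stop("load_config: plant block is required")
  spec_args <- list(above_ground_biomass = pl$above_ground_biomass,
                    management = pl$management, n_input = pl$n_input)
  if (!is.null(pl$ndf_above)) spec_args$ndf_above <- pl$ndf_above
  if (!is.null(pl$rs_ratio)) spec_args$rs_ratio_override <- pl$rs_ratio
  if (!is.null(pl$monthly_pattern))
    spec_args$monthly_pattern <- as.numeric(pl$monthly_pattern)
  if (!is.null(pl$ndf_by_month))
    spec_args$ndf_by_month <- as.numeric(pl$ndf_by_month)
  spec <- do.call(plant_residue_spec, spec_args)

  eom <- lapply(raw$eom, function(a) {
    app <- list(month = a$month, c_amount = a$c_amount)
    if (!is.null(a$lignin))
      app$quality <- eom_quality(a$lignin, a$holocellulose, a$solubles,
                                 label = if (is.null(a$label)) "config EOM"
                                         else a$label)
    app
  })

  mg <- raw$management
  po <- raw$poaching
  pp <- if (is.null(po)) poaching_params() else
    poaching_params(
      smd_threshold = if (is.null(po$smd_threshold_mm)) -10
                      else po$smd_threshold_mm,
      damage_per_lsu = if (is.null(po$damage_per_lsu)) 0.10
                       else po$damage_per_lsu,
      max_reduction = if (is.null(po$max_reduction)) 0.5
                      else po$max_reduction)

  rothc_config(
    version = if (is.null(raw$version)) "RothC_4" else raw$version,
    flags = if (is.null(raw$flags)) NULL else unlist(raw$flags),
    clay = site$clay, sand = site$sand,
    silt = if (is.null(site$silt)) 100 - site$clay - site$sand
           else site$silt,
    depth = if (is.null(site$depth_cm)) 20 else site$depth_cm,
    initial_soc = site$initial_soc,
    om = if (is.null(site$om)) 2.5 else site$om,
    plant = spec, eom_applications = eom,
    grazing_months = if (is.null(mg$grazing_months)) integer(0)
                     else as.integer(mg$grazing_months),
    stocking_rate = if (is.null(mg$stocking_rate)) 0
                    else mg$stocking_rate,
    vegetated_months = if (is.null(mg$vegetated_months)) 1:12
                       else as.integer(mg$vegetated_months),
    poaching = pp,
    evap_factor = if (is.null(raw$evap_factor)) 0.75 else raw$evap_factor
  )
}
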