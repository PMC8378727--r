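# Shared builders for scenario tests: a small deterministic weather series
# and a minimal grazed configuration.

flat_weather <- function(years = 2, tmean = 9, precip = 90, evap = 40,
                         start_year = 2004) {
  months <- rep(1:12, years)
  data.frame(year = rep(start_year + seq_len(years) - 1, each = 12),
             month = months,
             tmean_c = tmean - 6.5 * cos(2 * pi * (months - 1) / 12),
             precip_mm = precip, evap_mm = evap)
}

tiny_config <- function(version = "RothC_4", ...) {
  spec <- plant_residue_spec(above_ground_biomass = 7, management = "grazed",
                             n_input = 210)
  rothc_config(version = version, clay = 25, sand = 40, depth = 20,
               initial_soc = 90, plant = spec,
               eom_applications = list(
                 list(month = 6, c_amount = 1,
                      quality = ruminant_excreta_quality())),
               grazing_months = 5:10, stocking_rate = 1.5, ...)
}

run_version <- function(fixture, version) {
  cfg <- fixture$config
  cfg$version <- version
  cfg$flags <- rothc_version_flags(version)
  run_rothc(cfg, fixture$weather)
}
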