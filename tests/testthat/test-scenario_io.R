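test_that("version ladder presets are cumulative", {
  expect_equal(unname(rothc_version_flags("RothC_0")), rep(FALSE, 4))
  expect_equal(unname(rothc_version_flags("RothC_4")), rep(TRUE, 4))
  expect_equal(rothc_version_flags("RothC_2"),
               c(excreta_quality = TRUE, plant_residue = TRUE,
                 moisture_saturation = FALSE, poaching = FALSE))
  # each rung adds exactly one modification
  n_on <- vapply(paste0("RothC_", 0:4),
                 function(v) sum(rothc_version_flags(v)), numeric(1))
  expect_equal(unname(n_on), 0:4)
  expect_error(rothc_version_flags("RothC_9"), "unknown")
})

test_that("runs are deterministic and mass-balanced", {
  cfg <- tiny_config()
  w <- flat_weather(3)
  r1 <- run_rothc(cfg, w)
  r2 <- run_rothc(cfg, w)
  expect_identical(r1$monthly, r2$monthly)
  expect_lt(r1$mass_balance$rel_error, 1e-9)
  expect_equal(nrow(r1$monthly), 36)
  expect_equal(r1$annual$soc,
               r1$monthly$soc_total[r1$monthly$month == 12])
})

test_that("weather validation rejects gaps and missing columns", {
  w <- flat_weather(2)
  expect_error(run_rothc(tiny_config(), w[-15, ]), "gap")
  expect_error(run_rothc(tiny_config(), w[, -3]), "columns")
})

test_that("ladder ordering on a wet grazed fixture matches the wet-site pattern", {
  fx <- generate_fixture(101, "wet_grazed")
  socs <- vapply(paste0("RothC_", 0:4), function(v) {
    r <- run_version(fx, v)
    expect_lt(r$mass_balance$rel_error, 1e-9)
    r$annual$soc[nrow(r$annual)]
  }, numeric(1))
  # default version lowest; each substantive addition raises SOC;
  # poaching can only remove inputs
  expect_true(socs["RothC_0"] == min(socs[1:4]))
  expect_gt(socs["RothC_3"], socs["RothC_2"])
  expect_gt(socs["RothC_2"], socs["RothC_0"])
  expect_lte(socs["RothC_4"], socs["RothC_3"])
})

test_that("poaching is inert on dry and ungrazed fixtures", {
  fxd <- generate_fixture(5, "dry_grazed")
  r3 <- run_version(fxd, "RothC_3")
  r4 <- run_version(fxd, "RothC_4")
  expect_equal(sum(r4$monthly$poaching_flag), 0)
  expect_identical(r3$monthly$soc_total, r4$monthly$soc_total)
  fxc <- suppressMessages(generate_fixture(5, "wet_cut"))
  c3 <- run_version(fxc, "RothC_3")
  c4 <- suppressMessages(run_version(fxc, "RothC_4"))
  expect_identical(c3$monthly$soc_total, c4$monthly$soc_total)
})

test_that("wet grazed fixture saturates in every simulated year", {
  fx <- generate_fixture(77, "wet_grazed")
  r <- run_version(fx, "RothC_3")
  sat_months <- tapply(r$monthly$smd_mm <= -10, r$monthly$year, sum)
  expect_true(all(sat_months >= 1))
})

test_that("fixtures are pure functions of the seed", {
  a <- generate_fixture(123, "wet_grazed")
  b <- generate_fixture(123, "wet_grazed")
  expect_identical(a$weather, b$weather)
  expect_identical(a$observations, b$observations)
  expect_identical(a$config$flags, b$config$flags)
  c_ <- generate_fixture(124, "wet_grazed")
  expect_false(identical(a$weather$precip_mm, c_$weather$precip_mm))
})

test_that("results CSV round-trips bit-exactly", {
  fx <- generate_fixture(9, "wet_grazed", years = 2)
  r <- run_rothc(fx$config, fx$weather)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_results(r, path)
  back <- read_results(path)
  for (nm in names(r$monthly))
    expect_identical(back[[nm]], r$monthly[[nm]])
})

test_that("weather and observation CSV loaders validate schemas", {
  w <- flat_weather(2)
  wp <- tempfile(fileext = ".csv"); on.exit(unlink(wp), add = TRUE)
  utils::write.csv(w, wp, row.names = FALSE)
  expect_equal(nrow(load_weather(wp)), 24)
  utils::write.csv(w[-5, ], wp, row.names = FALSE)
  expect_error(load_weather(wp), "gap")
  utils::write.csv(w[, -4], wp, row.names = FALSE)
  expect_error(load_weather(wp), "precip_mm")
  op <- tempfile(fileext = ".csv"); on.exit(unlink(op), add = TRUE)
  utils::write.csv(data.frame(year = 2004:2006, soc = c(90, 91, 92)), op,
                   row.names = FALSE)
  expect_equal(load_observations(op)$soc, c(90, 91, 92))
  utils::write.csv(data.frame(year = 1, value = 2), op, row.names = FALSE)
  expect_error(load_observations(op), "soc")
})

test_that("structured config files load into equivalent configurations", {
  skip_if_not_installed("yaml")
  cfg_list <- list(
    version = "RothC_4",
    site = list(clay = 25, sand = 40, depth_cm = 20, initial_soc = 90),
    plant = list(management = "grazed", above_ground_biomass = 7,
                 n_input = 210),
    management = list(grazing_months = 5:10, stocking_rate = 1.5),
    eom = list(list(month = 6, c_amount = 1, lignin = 18.5,
                    holocellulose = 45, solubles = 36.5)),
    poaching = list(smd_threshold_mm = -10, damage_per_lsu = 0.1,
                    max_reduction = 0.5))
  yp <- tempfile(fileext = ".yaml"); on.exit(unlink(yp), add = TRUE)
  yaml::write_yaml(cfg_list, yp)
  cfg <- load_config(yp)
  ref <- tiny_config()
  w <- flat_weather(2)
  expect_equal(run_rothc(cfg, w)$monthly$soc_total,
               run_rothc(ref, w)$monthly$soc_total, tolerance = 1e-12)
  # JSON dialect loads identically
  skip_if_not_installed("jsonlite")
  jp <- tempfile(fileext = ".json"); on.exit(unlink(jp), add = TRUE)
  writeLines(jsonlite::toJSON(cfg_list, auto_unbox = TRUE), jp)
  cfg_j <- load_config(jp)
  expect_equal(run_rothc(cfg_j, w)$monthly$soc_total,
               run_rothc(ref, w)$monthly$soc_total, tolerance = 1e-12)
  expect_error(load_config(tempfile(fileext = ".txt")), "extension")
})

test_that("poaching without grazing is legal but flagged", {
  spec <- plant_residue_spec(7, "cut", 214)
  expect_message(
    rothc_config("RothC_4", clay = 25, sand = 40, initial_soc = 80,
                 plant = spec),
    "inert")
})

test_that("sensitivity sweeps honour domains and grid-density invariance", {
  fx <- generate_fixture(31, "wet_grazed", years = 3)
  expect_error(sweep_sensitivity(fx$config, fx$weather, "ndf", c(10, 70)),
               "within")
  expect_error(sweep_sensitivity(fx$config, fx$weather, "cover", c(0, 1)))
  # degenerate interval
  sw0 <- sweep_sensitivity(fx$config, fx$weather, "lignin", c(18, 18))
  expect_equal(sw0$index, 0)
  # monotone response: endpoints determine the index regardless of grid
  sw2 <- sweep_sensitivity(fx$config, fx$weather, "moisture_factor",
                           c(0.2, 1), n_points = 2)
  sw5 <- sweep_sensitivity(fx$config, fx$weather, "moisture_factor",
                           c(0.2, 1), n_points = 5)
  expect_equal(sw2$index, sw5$index, tolerance = 1e-9)
  # moisture dominates excreta quality at ~2.5 Mg C/yr of excreta
  swl <- sweep_sensitivity(fx$config, fx$weather, "lignin", c(9, 28))
  expect_gt(sw2$index, swl$index)
})
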