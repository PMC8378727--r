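test_that("temperature rate modifier: cutoff, closed form, monotonicity", {
  expect_identical(rate_modifier_temperature(-20), 0)
  expect_identical(rate_modifier_temperature(-18.27), 0)
  # hand evaluation of 47.91 / (1 + exp(106.06 / (9.25 + 18.27)))
  expect_equal(rate_modifier_temperature(9.25), 0.9940, tolerance = 1e-3)
  f <- rate_modifier_temperature(c(0, 5, 15))
  expect_true(f[3] > f[2] && f[2] > f[1])
  # continuity at the cutoff
  expect_lt(rate_modifier_temperature(-18.26), 1e-8)
  expect_error(rate_modifier_temperature(NaN), "finite")
})

test_that("cover factor retards decomposition under vegetation", {
  expect_identical(rate_modifier_cover(TRUE), 0.6)
  expect_identical(rate_modifier_cover(FALSE), 1.0)
  expect_identical(rate_modifier_cover(rep(TRUE, 12)), rep(0.6, 12))
})

test_that("decomposed-C partition conserves mass and follows the clay form", {
  z <- partition_decomposed(0, 25)
  expect_identical(unlist(z), c(co2 = 0, bio = 0, hum = 0))
  for (clay in c(0, 10, 23, 40, 80)) {
    p <- partition_decomposed(3.7, clay)
    expect_equal(p$co2 + p$bio + p$hum, 3.7, tolerance = 1e-14)
    x <- 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay))
    expect_equal(p$co2 / (p$bio + p$hum), x, tolerance = 1e-12)
    expect_equal(p$bio / p$hum, 46 / 54, tolerance = 1e-12)
  }
  # high-clay limit of the CO2 share: 1.67*1.85 / (1 + 1.67*1.85)
  p <- partition_decomposed(1, 100)
  expect_equal(p$co2, 1.67 * 1.85 / (1 + 1.67 * 1.85), tolerance = 1e-3)
  # retained share strictly increases with clay
  ret <- vapply(seq(0, 60, by = 5),
                function(cl) 1 - partition_decomposed(1, cl)$co2, numeric(1))
  expect_true(all(diff(ret) > 0))
  expect_error(partition_decomposed(-1, 25), "decomposed_c")
})

test_that("monthly step: frozen identity, pure inputs, annual closed form", {
  st <- carbon_state(dpm = 2, rpm = 20, bio = 3, hum = 60, iom = 10)
  # a = 0 halts decomposition entirely
  frozen <- step_month(st, list(a = 0, b = 1, c = 1), list(), clay = 25)
  expect_equal(unclass(frozen), unclass(st), tolerance = 1e-15)
  # inputs only: each entry pool gains exactly its allocation
  fed <- step_month(st, list(a = 0, b = 1, c = 1),
                    list(dpm = 0.5, rpm = 0.25, hum = 0.1), clay = 25)
  expect_equal(fed$dpm, st$dpm + 0.5)
  expect_equal(fed$rpm, st$rpm + 0.25)
  expect_equal(fed$hum, st$hum + 0.1)
  expect_equal(fed$bio, st$bio)
  # 12 monthly steps with constant modifiers == one annual decay
  mods <- list(a = 0.8, b = 0.7, c = 0.6)
  s <- carbon_state(rpm = 30, iom = 5)
  for (i in 1:12) s <- step_month(s, mods, list(), clay = 25)
  abc <- 0.8 * 0.7 * 0.6
  expect_equal(s$rpm, 30 * exp(-0.3 * abc), tolerance = 1e-12)
  expect_identical(s$iom, 5)
})

test_that("mass balance holds over randomised multi-step runs", {
  set.seed(42)
  for (rep in 1:20) {
    st <- carbon_state(dpm = runif(1, 0, 5), rpm = runif(1, 5, 30),
                       bio = runif(1, 0, 5), hum = runif(1, 20, 90),
                       iom = runif(1, 2, 12))
    clay <- runif(1, 5, 60)
    soc0 <- total_soc(st)
    total_in <- 0
    for (m in 1:24) {
      inp <- list(dpm = rexp(1, 10), rpm = rexp(1, 10), hum = rexp(1, 50))
      total_in <- total_in + inp$dpm + inp$rpm + inp$hum
      st <- step_month(st, list(a = runif(1, 0, 4), b = runif(1, 0.2, 1),
                                c = sample(c(0.6, 1), 1)), inp, clay = clay)
      expect_true(all(unlist(st[c("dpm", "rpm", "bio", "hum", "iom")]) >= 0))
    }
    delta <- total_soc(st) - soc0
    expect_lt(abs(delta - (total_in - st$cumulative_co2)) /
                max(total_in + st$cumulative_co2, soc0), 1e-9)
  }
})

test_that("with zero inputs and positive modifiers active SOC strictly falls", {
  st <- carbon_state(dpm = 1, rpm = 20, bio = 2, hum = 50, iom = 8)
  prev <- st$dpm + st$rpm + st$bio + st$hum
  for (m in 1:12) {
    st <- step_month(st, list(a = 1, b = 0.8, c = 0.6), list(), clay = 30)
    active <- st$dpm + st$rpm + st$bio + st$hum
    expect_lt(active, prev)
    expect_identical(st$iom, 8)
    prev <- active
  }
})

test_that("analytic monthly decay tracks a daily Euler oracle", {
  # independent brute-force oracle: 30 explicit-Euler sub-steps per month,
  # decay only (the BIO/HUM re-entry is covered by the mass-balance tests)
  euler_month <- function(pools, k, abc) {
    for (d in 1:30) pools <- pools * (1 - k * abc / 12 / 30)
    pools
  }
  k <- c(10, 0.3, 0.66, 0.02)
  st <- init_pools(100, 25)
  for (abc in c(0.3, 0.6, 1, 1.2)) {
    pools_a <- pools_e <- c(st$dpm, st$rpm, st$bio, st$hum)
    for (m in 1:12) {
      pools_a <- pools_a * exp(-k * abc / 12)
      pools_e <- euler_month(pools_e, k, abc)
    }
    expect_lt(abs(sum(pools_a) - sum(pools_e)) / sum(pools_e), 5e-3)
  }
})

test_that("default plant split reproduces the 1.44 DPM:RPM ratio", {
  sp <- default_plant_split()
  expect_equal(unname(sp["f_dpm"]), 1.44 / 2.44, tolerance = 1e-12)
  expect_equal(sum(sp), 1)
  expect_equal(unname(default_plant_split(0.67)["f_dpm"]), 0.67 / 1.67)
})

test_that("carbon_state and decay_constants validate their invariants", {
  expect_error(carbon_state(dpm = -1), "negative")
  expect_error(decay_constants(k_hum = 20), "ordering")
  expect_error(decay_constants(k_dpm = -1), "positive")
  st <- carbon_state(1, 2, 3, 4, 5)
  expect_equal(total_soc(st), 15)
})
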