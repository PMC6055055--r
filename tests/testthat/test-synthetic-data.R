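test_that("generated weather is diurnal, bounded and solar-consistent", {
  w <- generate_weather(latitude = 45, day_of_year = 180, par_peak = 2100,
                        seed = 7)
  expect_lte(max(w$par), 2100)
  expect_gte(min(w$par), 0)
  # PAR is zero while the sun is below the horizon
  sol <- solar_position(w$time, 45, 180)
  expect_true(all(w$par[sol$elevation <= 0] == 0))
  expect_true(all(w$par[w$time < 3 * 3600] == 0))
  # configured ranges honoured
  expect_equal(range(w$t_air), c(17.6, 35.9), tolerance = 1e-10)
  expect_equal(range(w$vp), c(1.7, 2.5), tolerance = 1e-10)
  expect_equal(range(w$co2), c(359.7, 439.4), tolerance = 1e-10)
  expect_true(all(w$vp <= svp(w$t_air)))
})

test_that("degenerate amplitudes give constant temperature and vapour", {
  w <- generate_weather(t_range = c(25, 25), vp_range = c(2, 2), seed = 3)
  expect_true(all(w$t_air == 25))
  expect_true(all(w$vp == 2))
})

test_that("weather generation is seed-deterministic and validates input", {
  w1 <- generate_weather(noise_sd = list(t_air = 0.5), seed = 11)
  w2 <- generate_weather(noise_sd = list(t_air = 0.5), seed = 11)
  w3 <- generate_weather(noise_sd = list(t_air = 0.5), seed = 12)
  expect_identical(w1, w2)
  expect_false(identical(w1$t_air, w3$t_air))
  expect_error(generate_weather(cadence_s = 1000), "divide 86400")
  expect_error(generate_weather(latitude = 120), "latitude")
  expect_error(generate_weather(day_of_year = 400), "day_of_year")
})

test_that("chamber simulation writes zero differentials for zero flux", {
  w <- fixture_weather()
  zero <- tibble::tibble(time = w$time, ec = 0, ac_net = 0)
  log <- simulate_chamber_series(w, zero)
  expect_true(all(log$vp_dif == 0))
  expect_true(all(log$co2_dif == 0))
})

test_that("chamber simulation inverts the transpiration mass balance", {
  # Ec = 0.886 mmol m-2 s-1 at VP_in = 2.00 kPa must log VP_dif ~ 0.10 kPa
  cfg <- system_config(u_e = 0.1757, a = 0.2, p = 101.3)
  w <- fixture_weather()[1, ]
  w$vp <- 2.00
  tf <- tibble::tibble(time = w$time, ec = 0.886, ac_net = 0)
  log <- simulate_chamber_series(w, tf, cfg)
  expect_equal(log$vp_dif, 0.10, tolerance = 1e-3)
  # and the computed flux returns the truth
  expect_equal(compute_ec(log$vp_in, log$vp_dif, cfg), 0.886,
               tolerance = 1e-12)
})

test_that("noisy logger signals give unbiased flux recovery", {
  cfg <- system_config()
  w <- fixture_weather()[rep(60, 1000), ]
  w$time <- seq_len(1000)
  tf <- tibble::tibble(time = w$time, ec = 0.886, ac_net = 5)
  log <- simulate_chamber_series(w, tf, cfg,
                                 noise_sd = list(vp_dif = 0.01), seed = 5)
  ec_hat <- compute_ec(log$vp_in, log$vp_dif, cfg)
  se <- sd(ec_hat) / sqrt(length(ec_hat))
  expect_lt(abs(mean(ec_hat) - 0.886), 2 * se)
})

test_that("grid mismatch between weather and fluxes is rejected", {
  w <- fixture_weather()
  tf <- tibble::tibble(time = w$time + 1, ec = 0, ac_net = 0)
  expect_error(simulate_chamber_series(w, tf), "time grids differ")
})

test_that("canopy profiles satisfy the extinction relations exactly", {
  pr <- generate_canopy_profile(sln0 = 2, kn = 0.5, kl = 0.96,
                                lai_total = 3, n_layers = 4)
  expect_equal(pr$rel_light, exp(-0.96 * pr$lai), tolerance = 1e-12)
  expect_equal(pr$sln, 2 * exp(-0.5 * pr$lai), tolerance = 1e-12)
  # cumulative N identity: N(L) = SLN0 (1 - exp(-kn L)) / kn
  expect_equal(pr$n_cum, 2 * (1 - exp(-0.5 * pr$lai)) / 0.5,
               tolerance = 1e-12)
  # at LAI = 1 with kL = 0.96, relative light is exp(-0.96)
  pr2 <- generate_canopy_profile(2, 0.5, 0.96, lai_total = 10 / 9,
                                 n_layers = 4)
  expect_equal(pr2$rel_light[pr2$lai == 10 / 9 * 0.5][1],
               exp(-0.96 * 10 / 9 * 0.5), tolerance = 1e-12)
})

test_that("uniform nitrogen profile and input validation", {
  pr <- generate_canopy_profile(sln0 = 1.5, kn = 0, kl = 0.9, lai_total = 2)
  expect_true(all(pr$sln == 1.5))
  expect_equal(pr$n_cum, 1.5 * pr$lai, tolerance = 1e-12)
  expect_error(generate_canopy_profile(2, kn = -0.1, kl = 0.9, lai_total = 2),
               "kn")
  expect_error(generate_canopy_profile(2, kn = 0.5, kl = 0, lai_total = 2),
               "kl")
})

test_that("night respiration samples follow the temperature response", {
  # at the 25 degC reference the rate equals rc25 exactly
  d <- generate_night_respiration(4, 9559, t_range = c(25, 25 + 1e-12),
                                  n = 3, seed = 1)
  expect_equal(d$rc, rep(4, 3), tolerance = 1e-9)
  d2 <- generate_night_respiration(4, 9559, t_range = c(14.7, 25.7),
                                   n = 200, seed = 2)
  expect_gte(min(d2$t_air), 14.7)
  expect_lte(max(d2$t_air), 25.7)
  expect_equal(d2$rc,
               respiration_at(d2$t_air, respiration_params(4, 9559)),
               tolerance = 1e-12)
  expect_error(generate_night_respiration(4, 9559, t_range = c(20, 20),
                                          n = 10),
               "unidentifiable")
})
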