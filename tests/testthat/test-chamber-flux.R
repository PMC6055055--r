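test_that("molar flow conversion and chamber residence time match the system", {
  # 4.3e-3 m3 s-1 at 25 degC, 101.3 kPa -> 101300 * 4.3e-3 / (8.314 * 298.15)
  expect_equal(molar_flow(4.3e-3, 25, 101.3),
               101.3e3 * 4.3e-3 / (8.314 * 298.15), tolerance = 1e-12)
  expect_equal(molar_flow(4.3e-3, 25, 101.3), 0.1757, tolerance = 1e-3)
  expect_equal(chamber_residence_time(system_config()), 0.3 / 4.3e-3,
               tolerance = 1e-12)
  expect_equal(chamber_residence_time(system_config()), 70, tolerance = 0.01)
})

test_that("transpiration mass balance evaluates exactly", {
  cfg <- system_config(u_e = 0.1757, a = 0.2, p = 101.3)
  expect_equal(compute_ec(2.0, 0, cfg), 0)
  # hand evaluation: 1000 * 0.1757 * 0.10 / (0.2 * (101.3 - 2.10))
  expect_equal(compute_ec(2.00, 0.10, cfg),
               1000 * 0.1757 * 0.10 / (0.2 * (101.3 - 2.10)),
               tolerance = 1e-12)
  expect_equal(compute_ec(2.00, 0.10, cfg), 0.886, tolerance = 1e-3)
  expect_error(compute_ec(101, 1, cfg), "pressure")
})

test_that("net photosynthesis mass balance evaluates exactly", {
  cfg <- system_config(u_e = 0.1757, a = 0.2)
  expect_equal(compute_ac_net(400, 0, ec = 0, cfg), 0)
  # hand evaluation: -(0.1757 * (-10) / 0.2 + 1e-3 * 0.886 * 390)
  expect_equal(compute_ac_net(400, -10, ec = 0.886, cfg),
               -(0.1757 * (-10) / 0.2 + 1e-3 * 0.886 * 390),
               tolerance = 1e-12)
  expect_equal(compute_ac_net(400, -10, ec = 0.886, cfg), 8.44,
               tolerance = 1e-2)
  expect_error(compute_ac_net(5, -10, ec = 0, cfg), "positive")
})

test_that("flux equations invert the synthetic generator to machine precision", {
  w <- fixture_weather()
  truth <- fixture_truth(w)
  cfg <- system_config()
  log <- simulate_chamber_series(w, truth, cfg)
  ec_hat <- compute_ec(log$vp_in, log$vp_dif, cfg)
  ac_hat <- compute_ac_net(log$co2_in, log$co2_dif, ec_hat, cfg)
  expect_equal(ec_hat, truth$ec, tolerance = 1e-10)
  expect_equal(ac_hat, truth$ac_net, tolerance = 1e-10)
})

test_that("spike filtering removes exactly the injected spikes", {
  w <- fixture_weather()
  truth <- fixture_truth(w)
  log <- simulate_chamber_series(w, truth,
                                 noise_sd = list(co2_dif = 0.2,
                                                 vp_dif = 0.002), seed = 9)
  # analyser noise also sits on the entrance signal
  set.seed(91)
  log$co2_in <- log$co2_in + rnorm(nrow(log), 0, 1.0)
  # clean series: nothing removed
  clean <- filter_records(log)
  expect_equal(sum(!clean$qc_keep), 0)
  # inject co2_in spikes far above the rejection threshold at 5 records
  spiked <- log
  idx <- c(20, 45, 70, 95, 110)
  spiked$co2_in[idx] <- spiked$co2_in[idx] + 60
  flagged <- filter_records(spiked)
  expect_equal(which(!flagged$qc_keep), idx)
  # all-constant series: zero spread handled without error, none removed
  const <- log
  const$co2_in <- 400
  const$vp_in <- 2
  expect_equal(sum(!filter_records(const)$qc_keep), 0)
  expect_error(filter_records(log[1:5, ], qc_policy(window = 7)),
               "window")
})

test_that("baseline correction subtracts the per-chamber empty-run mean", {
  w <- fixture_weather()
  truth <- fixture_truth(w)
  log <- simulate_chamber_series(w, truth)
  empty <- simulate_chamber_series(
    w, tibble::tibble(time = w$time, ec = 0, ac_net = 0))
  # zero-mean empty run leaves the series unchanged
  same <- correct_baseline(log, empty)
  expect_equal(same$co2_dif, log$co2_dif, tolerance = 1e-14)
  # constant leak of +0.5 umol/mol is removed exactly
  leaky <- empty
  leaky$co2_dif <- leaky$co2_dif + 0.5
  corr <- correct_baseline(dplyr::mutate(log, co2_dif = co2_dif + 0.5),
                           leaky)
  expect_equal(corr$co2_dif, log$co2_dif, tolerance = 1e-12)
  expect_warning(correct_baseline(log,
                                  dplyr::mutate(empty, chamber_id = "C99")),
                 "no empty run")
})

test_that("a known soil leak is recovered through baseline correction", {
  w <- fixture_weather()
  truth <- fixture_truth(w)
  cfg <- system_config()
  log <- simulate_chamber_series(w, truth, cfg)
  # soil efflux adds a constant offset on both signals
  log$co2_dif <- log$co2_dif + 1.2
  log$vp_dif <- log$vp_dif + 0.003
  empty <- simulate_chamber_series(
    w, tibble::tibble(time = w$time, ec = 0, ac_net = 0), cfg)
  empty$co2_dif <- empty$co2_dif + 1.2
  empty$vp_dif <- empty$vp_dif + 0.003
  corr <- correct_baseline(log, empty)
  ec_hat <- compute_ec(corr$vp_in, corr$vp_dif, cfg)
  expect_equal(ec_hat, truth$ec, tolerance = 1e-10)
})

test_that("respiration temperature response matches its closed form", {
  p <- respiration_params(4, 9559)
  expect_equal(respiration_at(25, p), 4, tolerance = 1e-12)
  expect_equal(respiration_at(35, p),
               4 * exp(9559 * 10 / (298 * 8.314 * 308)), tolerance = 1e-12)
  expect_equal(respiration_at(35, p), 4.53, tolerance = 1e-2)
  # monotone increasing in temperature for positive activation energy
  tt <- seq(5, 40, by = 0.5)
  expect_true(all(diff(respiration_at(tt, p)) > 0))
})

test_that("respiration fit recovers parameters from night data", {
  # noiseless: exact recovery
  d <- generate_night_respiration(4, 9559, n = 60, seed = 21)
  fit <- estimate_respiration(tibble::tibble(t_air = d$t_air, rc = d$rc))
  expect_equal(fit$params$rc25, 4, tolerance = 1e-6)
  expect_equal(fit$params$erc, 9559, tolerance = 1e-4)
  # noisy (sd = 1.0, n = 500): Rc25 within 5 %, ERc within its SE scale
  d2 <- generate_night_respiration(4, 9559, t_range = c(15, 26), n = 500,
                                   noise_sd = 1.0, seed = 22)
  fit2 <- estimate_respiration(d2)
  expect_lt(abs(fit2$params$rc25 - 4) / 4, 0.05)
  td <- tidy(fit2)
  se_erc <- td$std.error[td$term == "erc"]
  expect_lt(abs(fit2$params$erc - 9559), 3 * se_erc)
  expect_error(estimate_respiration(tibble::tibble(t_air = c(20, 20, 20),
                                                   rc = c(4, 4, 4))),
               "spread")
})

test_that("respiration-fit bias shrinks with sample size", {
  bias_at <- function(n) {
    reps <- vapply(1:30, function(r) {
      d <- generate_night_respiration(4, 9559, t_range = c(15, 26), n = n,
                                      noise_sd = 1.0, seed = 100 + r)
      estimate_respiration(d)$params$rc25
    }, numeric(1))
    abs(mean(reps) - 4)
  }
  expect_lt(bias_at(500), bias_at(50) + 0.02)
})

test_that("daily integration converts units and handles gaps", {
  tt <- seq(0, 86400 - 720, by = 720)
  const <- tibble::tibble(time = tt, chamber_id = "C01", ec = 1,
                          ac_net = 0, rc = 0, ac_gross = 0,
                          night = FALSE, qc_keep = TRUE)
  d <- daily_integrate(const)
  # 1 mmol m-2 s-1 over the sampled span: (86400 - 720) s * 1e-3
  expect_equal(d$ec_daily, (86400 - 720) / 1000, tolerance = 1e-12)
  expect_gt(d$coverage, 0.99)
  zero <- dplyr::mutate(const, ec = 0)
  expect_equal(daily_integrate(zero)$ec_daily, 0)
  # a 4-step gap is not bridged and lowers coverage
  gappy <- const[-(40:43), ]
  dg <- daily_integrate(gappy)
  expect_lt(dg$ec_daily, d$ec_daily)
  expect_lt(dg$coverage, d$coverage)
})

test_that("computed fluxes satisfy the gross = net + respiration identity", {
  w <- fixture_weather()
  truth <- fixture_truth(w)
  log <- simulate_chamber_series(w, truth)
  flux <- compute_fluxes(filter_records(log),
                         resp = respiration_params(4, 9559))
  day <- !flux$night
  expect_equal(flux$ac_gross[day], flux$ac_net[day] + flux$rc[day],
               tolerance = 1e-12)
  expect_true(all(flux$rc >= 0))
  expect_true(all(flux$ac_gross >= flux$ac_net - 1e-12))
  # at night gross photosynthesis is zero and Rc is read from the balance
  expect_true(all(flux$ac_gross[flux$night] == 0))
  expect_equal(flux$rc[flux$night], -flux$ac_net[flux$night],
               tolerance = 1e-10)
})

test_that("daily transpiration matches the water supplied in a mass-balance run", {
  # supply exactly half of potential: integrated Ec must equal the supply
  w <- fixture_weather()
  canopy <- canopy_state(2.3, 1.2, kn = 0.4)
  run_pot <- canopy_gas_exchange(canopy, w)
  supply <- 0.5 * run_pot$ec_pot
  run <- canopy_gas_exchange(canopy, w, water = supply)
  expect_equal(sum(run$ec) * 720 / 1000, sum(supply) * 720 / 1000,
               tolerance = 1e-10)
})
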