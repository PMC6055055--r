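test_that("solar geometry behaves at its landmarks", {
  # overhead sun at the equator on the equinox (DOY ~ 81)
  eq <- solar_position(12 * 3600, latitude = 0, day_of_year = 81)
  expect_gt(eq$elevation, 89)
  # no direct beam at night
  night <- solar_position(2 * 3600, 45, 180, par = 1000)
  expect_equal(night$par_dir, 0)
  # elevation symmetric about solar noon
  s1 <- solar_position(9 * 3600, 45, 180)
  s2 <- solar_position(15 * 3600, 45, 180)
  expect_equal(s1$elevation, s2$elevation, tolerance = 1e-9)
  expect_error(solar_position(0, latitude = 100, day_of_year = 10),
               "latitude")
})

test_that("sun/shade partitioning conserves area, light and nitrogen", {
  canopy <- canopy_state(3, 1.5, kn = 0.5)
  params <- leaf_params()
  fr <- partition_sunlit_shaded(canopy, elevation = 60, par_dir = 1200,
                                par_dif = 400, params = params)
  expect_equal(sum(fr$lai), 3, tolerance = 1e-12)
  # absorbed PAR cannot exceed incident PAR, and a denser canopy absorbs
  # more (multiple scattering lets canopy absorptance exceed that of a
  # single leaf, so incident light is the conservation bound)
  expect_lte(sum(fr$i_abs), 1200 + 400)
  expect_true(all(fr$i_abs >= 0))
  fr_sparse <- partition_sunlit_shaded(canopy_state(0.5, 1.5, kn = 0.5),
                                       60, 1200, 400, params)
  expect_lt(sum(fr_sparse$i_abs), sum(fr$i_abs))
  # nitrogen allocated to the fractions sums exactly to canopy N
  expect_equal(sum(fr$n_tot), canopy$nc, tolerance = 1e-10)
  # empty canopy -> empty fractions
  fr0 <- partition_sunlit_shaded(canopy_state(0, 1), 60, 1200, 400, params)
  expect_true(all(fr0$lai == 0) && all(fr0$i_abs == 0))
})

test_that("sunlit leaf area matches a fine numerical integration", {
  canopy <- canopy_state(3, 1.5, kn = 0.5)
  params <- leaf_params()
  for (elev in c(15, 40, 85)) {
    fr <- partition_sunlit_shaded(canopy, elev, 1000, 300, params)
    kb <- canopyflux:::kbeam(elev, params$leaf_angle)
    l <- seq(0, 3, length.out = 201)
    lai_sun_num <- sum(exp(-kb * (l[-1] + l[-201]) / 2) * diff(l))
    expect_equal(fr$lai[1], lai_sun_num, tolerance = 1e-3)
  }
})

test_that("the coupled leaf solution satisfies all three equations", {
  # supply (diffusion), biochemical demand and the conductance model must
  # agree at the returned operating point -- residual oracle
  params <- leaf_params()
  bio <- canopyflux:::biochem_at(28, 100, 190, 1.5, params)
  for (i_abs in c(50, 400, 1500)) {
    sol <- canopyflux:::solve_coupled(i_abs, 1.5, bio, ca = 400,
                                      vpd = 2, params)
    a_dem <- canopyflux:::fvcb_net(sol$ci, bio$vcmax, sol$j, bio$rd,
                                   bio$gamma_star, bio$km)
    a_sup <- sol$gsc * (400 - sol$ci)
    expect_equal(sol$a_net, a_dem, tolerance = 1e-7)
    expect_equal(sol$a_net, a_sup, tolerance = 1e-6)
    gs_model <- params$g0 * 1.5 + params$a1 * max(sol$a_net, 0) /
      ((400 - bio$gamma_star) * (1 + 2 / params$d0))
    expect_equal(sol$gsc, gs_model, tolerance = 1e-8)
  }
})

test_that("assimilation saturates with light and approaches the J limit at high CO2", {
  params <- leaf_params()
  bio <- canopyflux:::biochem_at(25, 100, 190, 1.5, params)
  a_of <- function(i_abs, ca = 400) {
    canopyflux:::solve_coupled(i_abs, 1.5, bio, ca, vpd = 1.5, params)$a_net
  }
  light <- c(0, 100, 300, 600, 1200, 2000)
  aa <- vapply(light, a_of, numeric(1))
  expect_true(all(diff(aa) > -1e-9))          # non-decreasing
  expect_lt(aa[6] - aa[5], aa[2] - aa[1])     # saturating
  expect_lte(aa[1], 0)                        # dark: respiration only
  # at saturating CO2 the rate approaches the electron-transport ceiling
  i2 <- 1500 * params$alpha_e
  jmax <- bio$jmax
  j <- (i2 + jmax - sqrt((i2 + jmax)^2 - 4 * params$theta_j * i2 * jmax)) /
    (2 * params$theta_j)
  a_inf <- canopyflux:::solve_coupled(1500, 1.5, bio, ca = 20000,
                                      vpd = 1.5, params)$a_net
  expect_equal(a_inf, j / 4 - bio$rd, tolerance = 0.02)
})

test_that("water-stress stomatal resistance follows its closed form", {
  # no stress: Ea = Ep returns the unstressed resistance exactly
  expect_equal(actual_stomatal_resistance(2, 2, 0.145, 25, 28, 100), 100)
  # hand arithmetic at half supply
  ep <- 2; ea <- 1
  expect_equal(actual_stomatal_resistance(ep, ea, 0.145, 25, 28, 100),
               (ep - ea) * (0.145 * 25 + 0.067 * 28) / (0.067 * ea) +
                 100 * ep / ea,
               tolerance = 1e-12)
  # strictly decreasing in available water
  ea_grid <- seq(0.1, 2, by = 0.1)
  r <- actual_stomatal_resistance(2, ea_grid, 0.145, 25, 28, 100)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= 100))
  expect_error(actual_stomatal_resistance(2, 0, 0.145, 25, 28, 100), "Ea")
  expect_error(actual_stomatal_resistance(2, 2.5, 0.145, 25, 28, 100),
               "exceed")
})

test_that("canopy fluxes vanish in the dark and for empty canopies", {
  w <- fixture_weather()
  canopy <- canopy_state(2.3, 1.2, kn = 0.4)
  run <- canopy_gas_exchange(canopy, w)
  night <- w$par == 0
  expect_true(all(run$ac_gross_pot[night] == 0))
  expect_true(all(run$ec_pot[night] < 0.5))    # residual conductance only
  expect_true(all(run$ec_pot >= 0))
  expect_true(all(run$ac_gross_pot >= 0))
  run0 <- canopy_gas_exchange(canopy_state(0, 1), w)
  expect_true(all(run0$ec_pot == 0) && all(run0$ac_gross_pot == 0))
})

test_that("ample water reproduces potential rates exactly and continuously", {
  w <- fixture_weather()[seq(30, 90, by = 10), ]
  canopy <- canopy_state(2.3, 1.2, kn = 0.4)
  pot <- canopy_gas_exchange(canopy, w)
  full <- canopy_gas_exchange(canopy, w, water = pot$ec_pot)
  expect_equal(full$ec, pot$ec_pot, tolerance = 1e-12)
  expect_equal(full$ac_gross, pot$ac_gross_pot, tolerance = 1e-12)
  # continuity: actual -> potential as the allowance approaches potential
  dev <- vapply(c(0.99, 0.999, 0.9999), function(f) {
    r <- canopy_gas_exchange(canopy, w, water_fraction = f)
    max(abs(r$ac_gross - r$ac_gross_pot) / pmax(r$ac_gross_pot, 1e-9))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.005)
})

test_that("halved water supply depresses midday fluxes below potential", {
  w <- fixture_weather()
  canopy <- canopy_state(2.3, 1.2, kn = 0.4)
  run <- canopy_gas_exchange(canopy, w, water_fraction = 0.5)
  late_morning <- w$time >= 11 * 3600 & w$time <= 17 * 3600
  expect_true(all(run$ec[late_morning] < run$ec_pot[late_morning]))
  expect_true(all(run$ac_gross[late_morning] <
                    run$ac_gross_pot[late_morning]))
  # photosynthesis falls less than proportionally to water: WUE rises
  pwue_act <- sum(run$ac_gross) / sum(run$ec)
  pwue_pot <- sum(run$ac_gross_pot) / sum(run$ec_pot)
  expect_gt(pwue_act, pwue_pot)
})

test_that("sun/shade totals agree with a 200-layer integration", {
  params <- leaf_params()
  for (lai in c(0.5, 2, 4, 6)) {
    canopy <- canopy_state(lai, 1.5, kn = 0.4)
    for (par in c(100, 500, 1000, 2000)) {
      sol <- solar_position(12.2 * 3600, 45, 180, par = par)
      w <- tibble::tibble(time = 12.2 * 3600, par = par, t_air = 28,
                          co2 = 400, vp = 2.2, wind = 0.5, p_atm = 101.3)
      two <- canopy_gas_exchange(canopy, w, params, latitude = 45,
                                 day_of_year = 180, leaf_temp = "air")
      ml <- multilayer_canopy(canopy, sol$elevation, sol$par_dir,
                              sol$par_dif, 28, 400, 2.2, 0.5, 101.3,
                              params)
      expect_equal(two$ac_gross_pot, ml[["ap"]], tolerance = 0.05)
      expect_equal(two$ec_pot, ml[["ep"]], tolerance = 0.05)
    }
  }
})
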