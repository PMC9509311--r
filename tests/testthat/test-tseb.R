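test_that("composite emissivity interpolates the component values", {
  expect_equal(composite_emissivity(1), 0.99)
  expect_equal(composite_emissivity(0), 0.94)
  expect_equal(composite_emissivity(0.5), 0.965)
  expect_error(composite_emissivity(1.2), "fc")
})

test_that("radiometric temperature inverts the longwave budget", {
  sigma <- 5.670374419e-8
  # full canopy: eps = 0.99
  lw_up <- 0.99 * sigma * 300^4 + 0.01 * 350
  expect_equal(lst_from_longwave(lw_up, 350, fc = 1), 300, tolerance = 1e-9)
  # bare soil at 290 K round-trips
  lw_up2 <- 0.94 * sigma * 290^4 + 0.06 * 320
  expect_equal(lst_from_longwave(lw_up2, 320, fc = 0), 290, tolerance = 1e-9)
  # increasing lw_in at fixed lw_up lowers the retrieved temperature
  expect_lt(lst_from_longwave(lw_up, 400, fc = 0.5),
            lst_from_longwave(lw_up, 300, fc = 0.5))
  expect_error(lst_from_longwave(3, 350, fc = 0.5), "non-physical")
})

test_that("fractional cover follows the gap-fraction law", {
  expect_equal(fractional_cover(0), 0)
  expect_equal(fractional_cover(1000), 1)
  expect_equal(fractional_cover(2), 1 - exp(-1))
  # clumping reduces cover at equal LAI
  expect_lt(fractional_cover(2, omega = 0.5), fractional_cover(2, omega = 1))
  # oblique view sees more canopy
  expect_gt(fractional_cover(2, view_zenith = 0.8), fractional_cover(2))
  expect_error(fractional_cover(2, view_zenith = pi / 2), "zenith")
  expect_error(fractional_cover(-1), "lai")
})

test_that("net radiation partition conserves energy and has the bare-soil
           limit", {
  surf <- surface_params()
  bare <- partition_net_radiation(800, 350, 300, 310,
                                  canopy_state(0, hc = 2), surf)
  expect_equal(bare$rn_c, 0)
  expect_equal(bare$rn_s, bare$rn)
  for (lai in c(0.5, 1.5, 3, 5)) {
    p <- partition_net_radiation(800, 350, 299, 305,
                                 canopy_state(lai, omega = 0.6), surf)
    expect_equal(p$rn_c + p$rn_s, p$rn, tolerance = 1e-9)
  }
  # more leaf area intercepts more radiation (fixed temperatures)
  p1 <- partition_net_radiation(800, 350, 299, 305, canopy_state(1), surf)
  p2 <- partition_net_radiation(800, 350, 299, 305, canopy_state(2), surf)
  expect_gt(p2$rn_c, p1$rn_c)
  expect_lt(p2$rn_s, p1$rn_s)
})

test_that("aerodynamic resistances match the neutral closed form and stay
           positive", {
  cs <- canopy_state(2, hc = 2)
  surf <- surface_params(z_u = 5, z_t = 5)
  r <- aerodynamic_resistances(3, cs, surf)
  # r_a = [ln((5 - 1.3)/0.25)]^2 / (0.41^2 * 3)
  expect_equal(r$r_a, log((5 - 1.3) / 0.25)^2 / (0.41^2 * 3),
               tolerance = 1e-10)
  expect_lt(abs(r$r_a - 14.4), 0.05)
  # r_a decreases with wind speed
  expect_lt(aerodynamic_resistances(5, cs, surf)$r_a, r$r_a)
  # positivity across a parameter grid, stable and unstable
  for (u in c(0.2, 1, 4)) {
    for (L in c(-20, -200, Inf, 200, 20)) {
      for (lai in c(0.1, 2, 5)) {
        rr <- aerodynamic_resistances(u, canopy_state(lai, omega = 0.6),
                                      surf, mo_length = L)
        expect_true(all(c(rr$r_a, rr$r_x, rr$r_s) > 0))
      }
    }
  }
  expect_error(aerodynamic_resistances(3, canopy_state(2, hc = 6), surf),
               "height")
})

test_that("the solver closes the energy budget with physical components", {
  met <- midday_met()
  for (lai in c(0.3, 1.5, 3.8)) {
    for (dt in c(1, 4, 8)) {
      cs <- canopy_state(lai, omega = 0.55)
      st <- solve_tseb_pt(met$t_air + dt, met, cs)
      resid <- (st$rn - st$g) - (st$h_c + st$h_s + st$le_c + st$le_s)
      expect_lt(abs(resid), 0.1)
      expect_gte(st$le_s, 0)
      expect_gte(st$alpha_pt, 0)
      expect_lte(st$alpha_pt, 1.26)
      # radiometric recomposition of the component temperatures
      t4 <- st$f_theta * st$t_c^4 + (1 - st$f_theta) * st$t_s^4
      expect_lt(abs(t4 - (met$t_air + dt)^4) / (met$t_air + dt)^4, 1e-6)
    }
  }
})

test_that("a well-watered canopy keeps the full Priestley-Taylor rate", {
  met <- midday_met(t_air = 295)
  cs <- canopy_state(2, omega = 0.8)
  st <- solve_tseb_pt(295 + 1.5, met, cs)   # cool scene: no stress
  expect_equal(st$alpha_pt, 1.26)
  tc <- 295 - 273.15
  delta <- 4098 * (0.6108 * exp(17.27 * tc / (tc + 237.3))) / (tc + 237.3)^2
  gamma <- 1005 * met$pressure / (0.622 * 2.45e6)
  expect_equal(st$le_c, 1.26 * delta / (delta + gamma) * st$rn_c,
               tolerance = 1e-9)
  expect_true(st$converged)
})

test_that("the sparse-canopy limit pins the soil to the radiometer", {
  met <- midday_met()
  st <- solve_tseb_pt(306, met, canopy_state(1e-6, omega = 0.5))
  expect_lt(abs(st$t_s - 306), 0.01)
  expect_lt(abs(st$le_c), 1e-3)
  expect_lt(abs(st$h_c), 1e-3)
})

test_that("daytime aggregation converts latent heat to water depth", {
  flux <- tibble::tibble(le_c = rep(245, 10), le_s = 0)
  agg <- daytime_et(flux)
  expect_equal(agg$et_mm, 245 * 3600 * 10 / 2.45e6)  # 3.6 mm
  expect_equal(agg$e_mm, 0)
  expect_equal(agg$et_mm, agg$t_mm + agg$e_mm)
  flux2 <- tibble::tibble(le_c = c(100, 200), le_s = c(50, 25))
  agg2 <- daytime_et(flux2)
  expect_equal(agg2$et_mm, agg2$t_mm + agg2$e_mm, tolerance = 1e-6)
  expect_error(daytime_et(flux2[0, ]), "empty")
})

test_that("residual closure correction adds the full residual to LE", {
  expect_equal(residual_closure_correction(500, 50, 150, 250), 300)
  # closed budget unchanged
  expect_equal(residual_closure_correction(500, 50, 150, 300), 300)
  # correction minus le equals the original residual
  rn <- 480; g <- 40; h <- 160; le <- 230
  expect_equal(residual_closure_correction(rn, g, h, le) - le,
               rn - g - h - le)
})

test_that("run_tseb_day solves every daytime hour of a simulated day", {
  met <- simulate_met_day(900, 296, 8, 1.4, 2.5, 101.3, lai = 2,
                          omega = 0.65, seed = 21)
  flux <- run_tseb_day(met, canopy_state(2, omega = 0.65))
  expect_equal(nrow(flux), sum(met$sw_in > 25))
  expect_true(all(flux$converged))
  expect_true(all(flux$le_s >= 0))
  agg <- daytime_et(flux)
  expect_gt(agg$et_mm, 1)     # plausible irrigated-vineyard daily ET
  expect_lt(agg$et_mm, 10)
})
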