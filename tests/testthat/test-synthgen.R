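test_that("reflectance simulation is seeded, bounded, and hits its limits", {
  arch <- site_archetypes()[1, ]
  r1 <- simulate_reflectance(arch, 1.5, seed = 5)
  r2 <- simulate_reflectance(arch, 1.5, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(unlist(r1) >= 0 & unlist(r1) <= 1))
  # zero LAI with zero noise returns the bare-soil endmember
  arch0 <- dplyr::mutate(arch, lai_min = 0)
  r0 <- simulate_reflectance(arch0, 0, noise_sd = 0)
  expect_equal(unlist(r0), arch$soil[[1]][names(unlist(r0))],
               tolerance = 1e-12)
  expect_error(simulate_reflectance(arch, 99), "range")
  # NDVI strictly increases with LAI at zero noise, every archetype
  all_arch <- site_archetypes()
  for (i in seq_len(nrow(all_arch))) {
    a <- all_arch[i, ]
    lai_grid <- seq(a$lai_min, a$lai_max, length.out = 15)
    ndvi <- vapply(lai_grid, function(l) {
      b <- simulate_reflectance(a, l, noise_sd = 0)
      (b$nir - b$red) / (b$nir + b$red)
    }, numeric(1))
    expect_true(all(diff(ndvi) > 0))
  }
})

test_that("the multi-site dataset reproduces the NDVI-window LAI contrast", {
  d <- simulate_lai_dataset(n_per_site = 400, seed = 42)
  expect_equal(nrow(d), 1200)
  expect_setequal(unique(d$site), c("BAR-like", "SLM-like", "RIP-like"))
  vi <- compute_vi(d)
  meds <- vi |>
    dplyr::filter(.data$ndvi >= 0.60, .data$ndvi <= 0.65) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(med = stats::median(.data$lai))
  med <- setNames(meds$med, meds$site)
  expect_lt(med[["BAR-like"]], med[["SLM-like"]])
  expect_lt(med[["SLM-like"]], med[["RIP-like"]])
  expect_lt(abs(med[["BAR-like"]] - 1.3), 0.4)
  expect_lt(abs(med[["SLM-like"]] - 1.7), 0.4)
  expect_lt(abs(med[["RIP-like"]] - 3.4), 0.4)
  expect_error(simulate_lai_dataset(site_archetypes()[0, ]), "archetypes")
  expect_error(simulate_lai_dataset(n_per_site = 10), "30")
})

test_that("a noise-free dataset is fit closely by a deeper model tree", {
  d <- simulate_lai_dataset(n_per_site = 150, seed = 13, noise_sd = 0)
  fit <- model_tree(d, max_rules = 12, min_leaf_n = 10)
  pred <- predict(fit, d)
  expect_lt(regression_metrics(pred, d$lai)$rmse, 0.05)
})

test_that("background samples saturate at the retrieval ceiling", {
  b <- simulate_background_samples(300, seed = 14, label_noise_sd = 0)
  expect_equal(nrow(b), 300)
  above <- b$lai_true > 4
  expect_equal(b$lai[above], rep(4, sum(above)))
  expect_equal(b$lai[!above], b$lai_true[!above])
  expect_identical(b, simulate_background_samples(300, seed = 14,
                                                  label_noise_sd = 0))
  expect_true(all(b$lai >= 0))
  bands <- dplyr::select(b, dplyr::all_of(semantic_bands()))
  expect_true(all(unlist(bands) >= 0 & unlist(bands) <= 1))
})

test_that("the simulated day is physically structured", {
  met <- simulate_met_day(900, 295, 8, 1.4, 2.5, 101.3, lai = 2,
                          omega = 0.65, seed = 3)
  expect_equal(nrow(met), 24)
  night <- met$time <= 6 | met$time >= 18
  expect_true(all(met$sw_in[night] == 0))
  expect_true(all(met$sw_in >= 0))
  expect_true(all(met$t_air > 250 & met$t_air < 330))
  expect_true(all(met$lw_in > 200 & met$lw_in < 500))
  # the radiometer inversion round-trips the generated longwave
  fc <- fractional_cover(2, 0.65)
  expect_equal(lst_from_longwave(met$lw_up, met$lw_in, fc), met$t_rad,
               tolerance = 1e-9)
  # unstressed closed canopy: radiometric excess bounded by a0 at noon
  met0 <- simulate_met_day(900, 295, 8, 1.4, 2.5, 101.3, lai = 50,
                           omega = 1, s = 0, t_rad_noise_sd = 0, seed = 3)
  noon <- met0[met0$time == 12, ]
  expect_lte(noon$t_rad - noon$t_air, 2 + 1e-9)
  expect_error(simulate_met_day(-5, 295, 8, 1.4, 2.5, 101.3, 2, 0.65),
               "peak_sw")
})

test_that("the IOP ensemble carries the printed baselines", {
  ens <- build_iop_ensemble(seed = 7)
  expect_equal(nrow(ens), 14)
  expect_equal(ens$lai[ens$scenario == "SLM001_2015_IOP1"], 0.51)
  expect_equal(ens$lai[ens$scenario == "RIP760_2018_IOP1"], 3.86)
  expect_setequal(unique(ens$site), c("BAR-like", "SLM-like", "RIP-like"))
  # deterministic given the seed
  ens2 <- build_iop_ensemble(seed = 7)
  expect_identical(ens$met, ens2$met)
  # clumping ordering: RIP < SLM < BAR
  om <- unique(ens[, c("site", "omega")])
  omv <- setNames(om$omega, om$site)
  expect_lt(omv[["RIP-like"]], omv[["SLM-like"]])
  expect_lt(omv[["SLM-like"]], omv[["BAR-like"]])
})
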