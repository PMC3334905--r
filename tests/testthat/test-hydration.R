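test_that("equilibrium droplet volume conserves the added precipitant", {
  # V_f = V_s / d: the droplet shrinks until its precipitant concentration
  # matches the reservoir, so only the moles added with the aliquot matter
  expect_equal(equilibrium_droplet_volume(standard_spec(1)), 450)
  expect_equal(equilibrium_droplet_volume(standard_spec(4)), 112.5)
  expect_equal(equilibrium_droplet_volume(standard_spec(7)), 64.29,
               tolerance = 1e-3)

  # independent of protein volume and of the absolute reservoir concentration
  expect_equal(
    equilibrium_droplet_volume(droplet_spec(9000, 450, 4, reservoir_conc = 2.8)),
    equilibrium_droplet_volume(standard_spec(4)))

  # precipitant conservation over random valid specs
  for (i in 1:50) {
    vs <- runif(1, 10, 1000)
    d <- runif(1, 1, 10)
    cr <- runif(1, 0.1, 5)
    spec <- droplet_spec(runif(1, 10, 1000), vs, d, cr)
    expect_equal(equilibrium_droplet_volume(spec) * cr, vs * cr / d)
  }
})

test_that("invalid droplet specifications are rejected", {
  expect_error(droplet_spec(0, 450, 1), "protein_volume")
  expect_error(droplet_spec(450, -1, 1), "screen_volume")
  expect_error(droplet_spec(450, 450, 0.5), "dilution_factor")
  expect_error(droplet_spec(450, 450, 1, reservoir_conc = 0), "reservoir_conc")
  expect_error(meso_system(0, 100), "mo_mass")
  expect_error(meso_system(132, -1), "water_mass")
})

test_that("hydration level is the water weight fraction of the system", {
  expect_equal(water_weight_fraction(meso_system(132, 900)), 87.2,
               tolerance = 1e-3)
  expect_equal(water_weight_fraction(meso_system(132, 0)), 0)
  expect_equal(water_weight_fraction(meso_system(132, 132)), 50)
  # monotone increasing in water mass
  w <- sort(runif(20, 0, 2000))
  h <- vapply(w, function(x) water_weight_fraction(meso_system(132, x)),
              numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("initial hydration treats the full aqueous volume as water", {
  expect_equal(round(initial_hydration(standard_spec(1),
                                       calibration_params(), 132)), 87)
  expect_equal(initial_hydration(droplet_spec(450, 450), calibration_params(),
                                 mo_mass = 29),
               96.9, tolerance = 1e-3)
})

test_that("expected final hydration reproduces the standard dilution series", {
  cal <- calibration_params(phi = 0.88)
  exact <- c(75, 60, 42.857143, 30)
  for (i in seq_len(nrow(caption_levels))) {
    res <- expected_final_hydration(standard_spec(caption_levels$dilution[i]),
                                    cal, standard_mo)
    expect_equal(res$hydration_pct, exact[i], tolerance = 1e-6)
    expect_identical(res$rounded_hydration_pct,
                     as.integer(caption_levels$hydration[i]))
    expect_equal(res$final_water_mass,
                 0.88 * 450 / caption_levels$dilution[i])
    expect_lte(res$final_droplet_volume, 900)
  }
})

test_that("final hydration is monotone in dilution and screen volume", {
  cal <- calibration_params(phi = 0.88)
  hyd <- function(d, vs) {
    expected_final_hydration(droplet_spec(450, vs, d), cal, 132)$hydration_pct
  }
  for (i in 1:25) {
    d1 <- runif(1, 1, 10); d2 <- d1 + runif(1, 0.1, 5)
    vs <- runif(1, 50, 2000)
    expect_gt(hyd(d1, vs), hyd(d2, vs))        # decreasing in d
    expect_gt(hyd(d1, vs * 1.5), hyd(d1, vs))  # increasing in V_s
  }
  # limits: vanishing lipid -> pure water; infinite dilution -> dry
  expect_equal(expected_final_hydration(standard_spec(1), cal,
                                        1e-9)$hydration_pct,
               100, tolerance = 1e-6)
  expect_lt(expected_final_hydration(standard_spec(1e9), cal,
                                     132)$hydration_pct, 1e-3)
})

test_that("phi calibration recovers the constant behind reported levels", {
  fit <- calibrate_phi(caption_levels, screen_volume = 450,
                       mo_mass = standard_mo)
  expect_lt(abs(fit$params$phi - 0.880), 0.005)
  expect_lt(fit$max_residual, 1)
  # agrees with an independent brute-force minimax grid search
  expect_lt(abs(fit$params$phi -
                  phi_grid_oracle(caption_levels, 450, standard_mo)), 0.001)
  # round trip: the fitted phi reproduces all reported integer levels
  for (i in seq_len(nrow(caption_levels))) {
    res <- expected_final_hydration(standard_spec(caption_levels$dilution[i]),
                                    fit$params, standard_mo)
    expect_identical(res$rounded_hydration_pct,
                     as.integer(caption_levels$hydration[i]))
  }
})

test_that("phi calibration closed form and degenerate inputs", {
  one <- calibrate_phi(data.frame(dilution = 1, hydration = 75), 450, 132)
  expect_equal(one$params$phi, 0.88, tolerance = 1e-12)
  expect_equal(one$max_residual, 0, tolerance = 1e-9)
  expect_error(
    calibrate_phi(data.frame(dilution = c(1, 1), hydration = c(75, 60)),
                  450, 132),
    "under-determined")
  expect_error(calibrate_phi(data.frame(dilution = numeric(),
                                        hydration = numeric()), 450, 132),
               "at least one")
})
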