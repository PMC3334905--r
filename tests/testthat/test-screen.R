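test_that("grid screens span both endpoints in row-major order", {
  g <- build_grid_screen(4.5, 8.5, 0.5, 4.0, n_pH = 8, n_conc = 12)
  expect_length(g, 96)
  expect_equal(c(g[[1]]$pH, g[[1]]$conc), c(4.5, 0.5))
  expect_equal(c(g[[96]]$pH, g[[96]]$conc), c(8.5, 4.0))
  expect_equal(g[[2]]$pH, 4.5)  # concentration varies within a pH row

  expect_length(build_grid_screen(5, 6, 1, 2, 2, 2), 4)
  expect_error(build_grid_screen(4.5, 8.5, 0.5, 4.0, 1, 1), "degenerate")
  expect_error(build_grid_screen(8.5, 4.5, 0.5, 4.0, 8, 12), "min < max")
  expect_warning(big <- build_grid_screen(4.5, 8.5, 0.5, 4.0, 9, 12),
                 "split over 2 plates")
  expect_equal(max(attr(big, "plate")), 2L)
})

test_that("additive mixing dilutes the base and keeps fractions normalized", {
  base <- screen_solution("ammonium sulfate", 4.0)
  mixed <- with_additive(base, "sodium malonate", stock_conc = 1000,
                         unit = "mM", fraction = 0.10)
  expect_equal(mixed$conc, 3.6)  # 90 parts base + 10 parts additive
  expect_equal(mixed$additives$conc, 100)
  expect_equal(sum(mixed$fractions), 1)
  expect_equal(unname(mixed$fractions["sodium malonate"]), 0.10)

  expect_identical(with_additive(base, "x", 1, fraction = 0), base)
  expect_error(with_additive(base, "x", 1, fraction = 1), "< 1")

  # a second additive rescales the first
  twice <- with_additive(mixed, "glycerol", stock_conc = 50, unit = "% (v/v)",
                         fraction = 0.10)
  expect_equal(twice$additives$conc[1], 90)
  expect_equal(sum(twice$fractions), 1)
})

test_that("screen dilution divides every solute concentration", {
  stock <- screen_solution("ammonium sulfate", 3.4,
                          additives = data.frame(name = "sodium malonate",
                                                 conc = 380, unit = "mM"))
  half <- dilute_screen(stock, 2)
  expect_equal(half$conc, 1.7)
  expect_equal(half$additives$conc, 190)
  expect_equal(dilute_screen(stock, 1), stock)
  expect_equal(dilute_screen(screen_solution("phosphate", 2.8), 4)$conc, 0.7)
  expect_error(dilute_screen(stock, 0.5), "'d'")
})

test_that("plate planning carries volumes, protein mass and predictions", {
  plate <- plan_plate(16, screen_solution("phosphate", 2.8, pH = 5.6),
                      format = "mo132", dilutions = c(1, 4, 7))
  expect_equal(unique(plate$wells$protein_mass), 7.2)
  expect_equal(plate$wells$well, c("A1", "A2", "A3"))
  expect_equal(plate$timeline$swelling_hours, 3)

  small <- plan_plate(16, screen_solution("phosphate", 2.8), format = "mo29")
  expect_equal(small$wells$protein_mass, 1.6)

  # predictions agree with direct calls into the other modules
  cal <- calibration_params()
  for (i in seq_len(nrow(plate$wells))) {
    d <- plate$wells$dilution_factor[i]
    res <- expected_final_hydration(droplet_spec(450, 450, d), cal, 132)
    expect_equal(plate$wells$predicted_hydration[i], res$hydration_pct)
    expect_equal(plate$wells$phase[i],
                 classify_phase(res$hydration_pct)$phase)
  }

  # protein accounting sums per-well volume x concentration
  g <- build_grid_screen(4.5, 8.5, 0.5, 4.0, 8, 12)
  full <- plan_plate(16, g, dilutions = 4)
  expect_equal(protein_consumption(full), 96 * 7.2)

  empty <- plan_plate(16, list())
  expect_equal(nrow(empty$wells), 0L)
  expect_no_error(validate_plate_layout(empty))

  expect_error(plan_plate(16, g, dilutions = c(1, 4)), "do not fit")
})

test_that("plate validator names offending wells", {
  plate <- plan_plate(16, screen_solution("phosphate", 2.8), dilutions = 4)
  plate$wells$mo_mass <- 29
  expect_error(validate_plate_layout(plate), "A1")
  plate2 <- plan_plate(16, screen_solution("phosphate", 2.8),
                       dilutions = c(1, 2))
  plate2$wells$well <- c("A1", "A1")
  expect_error(validate_plate_layout(plate2), "duplicated")
})

test_that("worklists have one dispensing step per reagent per well", {
  one <- plan_plate(16, screen_solution("phosphate", 2.8), dilutions = 4)
  wl <- export_worklist(one)
  expect_equal(nrow(wl), 3L)
  expect_equal(wl$step, c("protein", "screen_diluted", "reservoir"))
  expect_equal(wl$volume_nl, c(450L, 450L, 75000L))
  expect_true(is.integer(wl$volume_nl))

  g <- build_grid_screen(4.5, 8.5, 0.5, 4.0, 8, 12)
  full <- export_worklist(plan_plate(16, g, dilutions = 4))
  expect_equal(nrow(full), 288L)
  # protocol order: all protein steps precede all screen/reservoir steps
  expect_true(all(diff(full$step_order) >= 0))
})

test_that("worklist export/import is a bit-exact round trip", {
  base <- screen_solution("ammonium sulfate", 3.4,
                          additives = data.frame(name = "sodium malonate",
                                                 conc = 380, unit = "mM"))
  screens <- list(base, with_additive(base, "glycerol", 100, "% (v/v)"))
  plate <- plan_plate(31, screens, format = "mo132", dilutions = c(2, 4))

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_worklist(export_worklist(plate), p1)
  back <- import_worklist(read_worklist(p1))
  write_worklist(export_worklist(back), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(back$wells, plate$wells)
  expect_equal(back$screens, plate$screens)

  bad <- withr::local_tempfile(fileext = ".csv")
  wl <- read_worklist(p1)
  writeLines(c(paste(names(wl), collapse = ","),
               "1,protein,protein_sample,A1,not_a_volume,mo132,31,0.88,1,x,3.4,NA,,base=1,2"),
             bad)
  expect_error(read_worklist(bad), "row")
})
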