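test_that("fraction incorporated follows the partitioning model", {
  sys40 <- meso_system(132, 88)  # 40 wt% water on the standard coating
  expect_equal(fraction_incorporated(partition_params(0), sys40), 0)
  expect_equal(fraction_incorporated(partition_params(25), sys40), 0.974026,
               tolerance = 1e-6)
  expect_equal(fraction_incorporated(partition_params(0.1), sys40),
               13.2 / 101.2, tolerance = 1e-9)
  expect_equal(fraction_incorporated(partition_params(Inf), sys40), 1)
  # no aqueous pool left: everything is incorporated
  expect_equal(fraction_incorporated(partition_params(3), meso_system(132, 0)), 1)
  expect_error(partition_params(-1), "'K'")
})

test_that("fraction incorporated matches the mole-conservation oracle", {
  set.seed(42)
  for (i in 1:40) {
    K <- 10^runif(1, -2, 3)
    M <- runif(1, 10, 500)
    W <- runif(1, 1, 2000)
    expect_equal(fraction_incorporated(partition_params(K),
                                       meso_system(M, W)),
                 fraction_oracle(K, M, W), tolerance = 1e-9)
  }
  # exact conservation: lipid-phase + aqueous protein = total applied
  K <- 7; M <- 132; W <- 250; total <- 5.3
  f <- fraction_incorporated(partition_params(K), meso_system(M, W))
  expect_identical(f * total + (1 - f) * total, total)
})

test_that("aqueous concentration ratio is capped by the K = 0 limit", {
  # ideally diluted limit: no incorporation, d-fold up-concentration
  expect_equal(aqueous_concentration_ratio(0, standard_spec(4),
                                           meso_system(132, 0.88 * 450 / 4)),
               4)
  expect_equal(aqueous_concentration_ratio(0, standard_spec(1),
                                           meso_system(132, 0.88 * 450)),
               1)
  r50 <- aqueous_concentration_ratio(50, standard_spec(1),
                                     meso_system(132, 396))
  expect_equal(r50, 0.0566, tolerance = 1e-3)
  # chained check against the fraction formula
  expect_equal(r50, (1 - 6600 / 6996) * 450 * 1 / 450, tolerance = 1e-12)
  for (K in c(0.01, 0.5, 2, 25, 300)) {
    for (d in c(1, 4, 7)) {
      sys <- meso_system(132, 0.88 * 450 / d)
      expect_lte(aqueous_concentration_ratio(K, standard_spec(d), sys),
                 aqueous_concentration_ratio(0, standard_spec(d), sys))
    }
  }
})

test_that("incorporation thresholds hold across the regime boundaries", {
  # strong partitioning (K >= 25) keeps >= 90% in the lipid phase at or
  # below 40 wt% water; weak partitioning (K <= 0.1) stays below 30% there
  for (K in c(25, 50, 125, 1000)) {
    for (w_pct in c(5, 20, 40)) {
      W <- 132 * w_pct / (100 - w_pct)
      expect_gte(fraction_incorporated(partition_params(K),
                                       meso_system(132, W)), 0.9)
    }
  }
  for (K in c(0.1, 0.05, 0.01)) {
    for (w_pct in c(40, 60, 87)) {
      W <- 132 * w_pct / (100 - w_pct)
      expect_lte(fraction_incorporated(partition_params(K),
                                       meso_system(132, W)), 0.3)
    }
  }
})

test_that("estimate_K inverts the depletion measurement", {
  # no depletion
  expect_equal(estimate_K(partition_assay(16, 900, 132, 16))$K, 0)
  # forward-simulated K = 50 assay: C_sup/C_0 = 0.12 exactly
  expect_equal(estimate_K(partition_assay(16, 900, 132, 16 * 0.12))$K, 50,
               tolerance = 1e-12)
  # exact noiseless round trip over a log grid of true constants
  for (K in 10^seq(-2, 3, by = 0.5)) {
    f <- K * 132 / (K * 132 + 900)
    est <- estimate_K(partition_assay(16, 900, 132, 16 * (1 - f)))
    expect_equal(est$K, K, tolerance = 1e-9)
  }
})

test_that("estimate_K flags boundary and impossible measurements", {
  depleted <- estimate_K(partition_assay(16, 900, 132, 0))
  expect_identical(depleted$K, Inf)
  expect_match(depleted$replicates$flag, "unbounded")
  expect_warning(over <- estimate_K(partition_assay(16, 900, 132, 17)),
                 "exceeds sample")
  expect_equal(over$K, 0)
  expect_true(partition_assay(16, 900, 132, 17)$flagged)
  # replicates with different applied volumes are estimated per row
  est <- estimate_K(partition_assay(16, c(900, 450), 132,
                                    16 * c(1 - 6600 / 7500, 1 - 6600 / 7050)))
  expect_equal(est$replicates$K_hat, c(50, 50), tolerance = 1e-9)
})

test_that("bootstrap interval behaves and is seed-deterministic", {
  same <- partition_assay(16, 900, 132, rep(16 * 0.12, 5))
  ci <- bootstrap_K_interval(same, n_resamples = 200, seed = 3)
  expect_equal(ci$lower, ci$upper)

  a <- simulate_partition_assay(synthetic_assay_spec(50, noise_cv = 0.05,
                                                     n_replicates = 8,
                                                     seed = 1))
  ci1 <- bootstrap_K_interval(a, seed = 11)
  ci2 <- bootstrap_K_interval(a, seed = 11)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, 50)
  expect_gte(ci1$upper, 50)

  expect_error(bootstrap_K_interval(partition_assay(16, 900, 132, c(1, 2))),
               "at least 3")
  expect_error(bootstrap_K_interval(same, n_resamples = 0), "n_resamples")
})

test_that("assay CSV round trips and reports missing columns", {
  a <- simulate_partition_assay(synthetic_assay_spec(25, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(a, path)
  b <- read_assay_csv(path)
  expect_equal(b$supernatant_conc, a$supernatant_conc)
  expect_equal(suppressWarnings(estimate_K(b)$K),
               suppressWarnings(estimate_K(a)$K))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("well,sample_conc_ug_ul\nA1,16", bad)
  expect_error(read_assay_csv(bad), "missing column")
})
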