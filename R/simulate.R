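#' Specification of a synthetic partitioning assay
#'
#' Ground-truth description of a depletion assay to simulate: a known true
#' partitioning constant, the applied protein solution, the monoolein mass
#' per well, and a multiplicative lognormal measurement noise on the
#' photometric supernatant readout. The seed fixes the full output; there
#' is no hidden global random state.
#'
#' @param K_true True partitioning constant (`>= 0`).
#' @param sample_conc Applied protein concentration, ug/ul.
#' @param applied_volume Applied volume per well, nl.
#' @param mo_mass Monoolein mass per well, ug.
#' @param n_replicates Number of replicate wells.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (default 0.05); `0` gives the exact forward model.
#' @param seed Integer seed.
#' @return An object of class `synthetic_assay_spec`.
#' @export
synthetic_assay_spec <- function(K_true, sample_conc = 16,
                                 applied_volume = 900, mo_mass = 132,
                                 n_replicates = 8, noise_cv = 0.05,
                                 seed = 1) {
  check_number(K_true, "K_true", lower = 0)
  check_number(sample_conc, "sample_conc", lower = .Machine$double.xmin)
  check_number(applied_volume, "applied_volume", lower = .Machine$double.xmin)
  check_number(mo_mass, "mo_mass", lower = .Machine$double.xmin)
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(noise_cv, "noise_cv", lower = 0)
  structure(list(K_true = K_true, sample_conc = sample_conc,
                 applied_volume = applied_volume, mo_mass = mo_mass,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synthetic_assay_spec")
}

#' Simulate a partitioning depletion assay with known K
#'
#' Forward-computes the incorporated fraction from the true constant via
#' [fraction_incorporated()] (total water = applied volume, as in the
#' sealed assay), sets the expected supernatant concentration to
#' `(1 - f) * C_0`, and perturbs each replicate with multiplicative
#' lognormal noise of the requested CV (unit mean, so the noiseless limit
#' is recovered exactly at `noise_cv = 0`).
#'
#' @param spec A [synthetic_assay_spec()].
#' @return A [partition_assay()].
#' @examples
#' a <- simulate_partition_assay(synthetic_assay_spec(K_true = 50, seed = 7))
#' estimate_K(a)
#' @export
simulate_partition_assay <- function(spec) {
  stopifnot(inherits(spec, "synthetic_assay_spec"))
  f <- fraction_incorporated(partition_params(spec$K_true),
                             meso_system(spec$mo_mass, spec$applied_volume))
  c_sup <- (1 - f) * spec$sample_conc
  noise <- if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    withr::with_seed(spec$seed,
                     exp(rnorm(spec$n_replicates, -sdlog^2 / 2, sdlog)))
  } else rep(1, spec$n_replicates)
  partition_assay(sample_conc = spec$sample_conc,
                  applied_volume = spec$applied_volume,
                  mo_mass = spec$mo_mass,
                  supernatant_conc = c_sup * noise)
}

#' Simulate reported calibration observations
#'
#' Generates (dilution factor, hydration level) pairs from the forward
#' equilibration model at a known `phi`, optionally integer-rounded the
#' way hydration levels are reported. These are the fixtures
#' [calibrate_phi()] is tested against: unrounded observations invert
#' exactly, rounded ones to within the rounding error.
#'
#' @param true_phi The `phi` used by the forward model, ug/nl.
#' @param dilutions Distinct dilution factors.
#' @param screen_volume Screen aliquot volume, nl.
#' @param mo_mass Monoolein mass, ug.
#' @param rounded Round hydration to integer percent (half up)?
#' @return Data frame with columns `dilution` and `hydration`.
#' @examples
#' simulate_calibration_observations(0.88, c(1, 2, 4, 7))
#' @export
simulate_calibration_observations <- function(true_phi, dilutions,
                                              screen_volume = 450,
                                              mo_mass = 132,
                                              rounded = TRUE) {
  check_number(true_phi, "true_phi", lower = .Machine$double.xmin, upper = 1.1)
  if (anyDuplicated(dilutions)) stop_invalid("dilution factors must be distinct")
  h <- hydration_from_phi(true_phi, dilutions, screen_volume, mo_mass)
  if (rounded) h <- round_half_up(h)
  data.frame(dilution = dilutions, hydration = h)
}

#' Deterministic demo fixture bundle
#'
#' Builds, from one seed, the complete set of artifacts the package
#' produces: a 96-condition phosphate grid-screen plate, an
#' additive-optimization plate around an ammonium sulfate condition
#' (10 percent v/v additive content), a synthetic partitioning assay with
#' known `K_true = 50`, and the grid plate's worklist. Identical seeds
#' give identical output.
#'
#' @param seed Integer seed (drives the synthetic assay noise).
#' @return A list with elements `grid_plate`, `additive_plate`, `assay`,
#'   `assay_spec` and `worklist`.
#' @export
make_demo_plate <- function(seed = 1) {
  grid <- build_grid_screen(4.5, 8.5, 0.5, 4.0, n_pH = 8, n_conc = 12)
  grid_plate <- plan_plate(16, grid, format = "mo132", dilutions = 4,
                           metadata = list(protein = "demo membrane protein"))

  base <- screen_solution("ammonium sulfate", 4.0)
  additives <- c("sodium malonate", "sodium citrate", "potassium chloride",
                 "magnesium chloride", "PEG 400", "glycerol")
  additive_screens <- c(list(base),
                        lapply(additives, function(a) {
                          with_additive(base, a, stock_conc = 1000,
                                        unit = "mM", fraction = 0.10)
                        }))
  additive_plate <- plan_plate(16, additive_screens, format = "mo29",
                               dilutions = c(1, 2, 4, 7),
                               metadata = list(protein = "demo membrane protein"))

  assay_spec <- synthetic_assay_spec(K_true = 50, sample_conc = 16,
                                     applied_volume = 900, mo_mass = 132,
                                     n_replicates = 8, noise_cv = 0.05,
                                     seed = seed)
  list(grid_plate = grid_plate,
       additive_plate = additive_plate,
       assay = simulate_partition_assay(assay_spec),
       assay_spec = assay_spec,
       worklist = export_worklist(grid_plate))
}
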