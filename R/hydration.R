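#' Condensed monoolein/water system
#'
#' The state of the condensed system in one well: the mass of monoolein
#' `M` deposited as the plate coating and the total mass of water `W` it is
#' in contact with. The hydration level (weight percent water of the
#' water + monoolein system) computed from this state is what selects the
#' mesophase.
#'
#' @param mo_mass Monoolein mass in ug (`M > 0`).
#' @param water_mass Total water mass in ug (`W >= 0`).
#' @return An object of class `meso_system`.
#' @examples
#' meso_system(mo_mass = 132, water_mass = 396)
#' @export
meso_system <- function(mo_mass, water_mass) {
  check_number(mo_mass, "mo_mass", lower = .Machine$double.xmin)
  check_number(water_mass, "water_mass", lower = 0)
  structure(list(mo_mass = mo_mass, water_mass = water_mass),
            class = "meso_system")
}

#' @export
print.meso_system <- function(x, ...) {
  cat(sprintf("<meso_system> %g ug monoolein + %g ug water (%.1f wt%% water)\n",
              x$mo_mass, x$water_mass, water_weight_fraction(x)))
  invisible(x)
}

#' Specification of one vapor-diffusion crystallization droplet
#'
#' Describes the aqueous side of a standard experiment: a protein drop of
#' volume `protein_volume` is dispensed onto the lipid coating; after the
#' swelling phase a screening solution aliquot of volume `screen_volume`,
#' diluted `dilution_factor`-fold relative to the reservoir, is added, and
#' the sealed well equilibrates against undiluted reservoir solution.
#'
#' @param protein_volume Protein solution volume in nl.
#' @param screen_volume Screening solution volume in nl.
#' @param dilution_factor Dilution of the added screen aliquot relative to
#'   the reservoir; `1` means undiluted, `4` means diluted 1:4. Must be
#'   `>= 1` (the droplet can only be less concentrated than the reservoir).
#' @param reservoir_conc Precipitant concentration of the reservoir in
#'   mol/l. The equilibrium droplet volume does not depend on its absolute
#'   value, only on the dilution factor; it is carried for bookkeeping.
#' @return An object of class `droplet_spec`.
#' @examples
#' droplet_spec(450, 450, dilution_factor = 4)
#' @export
droplet_spec <- function(protein_volume, screen_volume, dilution_factor = 1,
                         reservoir_conc = 1) {
  check_number(protein_volume, "protein_volume", lower = .Machine$double.xmin)
  check_number(screen_volume, "screen_volume", lower = .Machine$double.xmin)
  check_number(dilution_factor, "dilution_factor", lower = 1)
  check_number(reservoir_conc, "reservoir_conc", lower = .Machine$double.xmin)
  structure(list(protein_volume = protein_volume,
                 screen_volume = screen_volume,
                 dilution_factor = dilution_factor,
                 reservoir_conc = reservoir_conc),
            class = "droplet_spec")
}

#' Calibration constants of the equilibration mass balance
#'
#' `phi` is the effective water mass per unit droplet volume at the
#' vapor-diffusion endpoint, in ug/nl. It is below the density of pure
#' water because the equilibrated droplet carries the full reservoir
#' concentration of precipitant, whose mass fraction `phi` absorbs. The
#' default 0.88 is what [calibrate_phi()] recovers from the published
#' expected hydration levels of the standard 132 ug experiment.
#'
#' @param phi Effective water mass per nl of equilibrated droplet
#'   (0 < phi <= 1.1).
#' @param water_density_initial Density of the pre-equilibration aqueous
#'   phase in ug/nl; the dilute starting droplet is taken as pure water
#'   (default 1.0).
#' @return An object of class `calibration_params`.
#' @export
calibration_params <- function(phi = 0.88, water_density_initial = 1.0) {
  check_number(phi, "phi", lower = .Machine$double.xmin, upper = 1.1)
  check_number(water_density_initial, "water_density_initial",
               lower = .Machine$double.xmin)
  structure(list(phi = phi, water_density_initial = water_density_initial),
            class = "calibration_params")
}

#' Droplet volume at the vapor-diffusion endpoint
#'
#' During equilibration the droplet loses water through the vapor phase
#' until its precipitant concentration matches the reservoir. The moles of
#' precipitant added with the screen aliquot, `screen_volume * C_R / d`,
#' are conserved, so the endpoint volume is determined entirely by the
#' amount of precipitating agent added:
#' `V_f = screen_volume / dilution_factor`. It is independent of the
#' protein volume and of the absolute reservoir concentration.
#'
#' @param spec A [droplet_spec()].
#' @return Final droplet volume in nl.
#' @examples
#' equilibrium_droplet_volume(droplet_spec(450, 450, 4)) # 112.5 nl
#' @export
equilibrium_droplet_volume <- function(spec) {
  stopifnot(inherits(spec, "droplet_spec"))
  spec$screen_volume / spec$dilution_factor
}

#' Hydration level of a monoolein/water system
#'
#' The weight percent of water in the water + monoolein system,
#' `100 * W / (W + M)`. This is the axis along which the mesophase
#' sequence (Lc, L-alpha, Ia3d, Pn3m, Pn3m + excess water) unfolds.
#'
#' @param system A [meso_system()].
#' @return Hydration in wt percent water.
#' @examples
#' water_weight_fraction(meso_system(132, 900)) # 87.2
#' @export
water_weight_fraction <- function(system) {
  stopifnot(inherits(system, "meso_system"))
  100 * system$water_mass / (system$water_mass + system$mo_mass)
}

#' Hydration level at the start of the experiment
#'
#' Before equilibration the full aqueous volume (protein plus screen
#' aliquot) hydrates the lipid; the dilute starting droplet is treated as
#' water of density `water_density_initial`. For the standard experiment
#' (450 + 450 nl on 132 ug monoolein) this gives 87 wt percent.
#'
#' @param spec A [droplet_spec()].
#' @param cal A [calibration_params()].
#' @param mo_mass Monoolein mass in ug.
#' @return Initial hydration in wt percent.
#' @export
initial_hydration <- function(spec, cal = calibration_params(), mo_mass) {
  stopifnot(inherits(spec, "droplet_spec"), inherits(cal, "calibration_params"))
  w <- (spec$protein_volume + spec$screen_volume) * cal$water_density_initial
  water_weight_fraction(meso_system(mo_mass, w))
}

#' Expected hydration level at the vapor-diffusion endpoint
#'
#' The endpoint droplet volume is `screen_volume / d` (see
#' [equilibrium_droplet_volume()]); its water mass is `phi` times that
#' volume, where `phi` accounts for the precipitant mass fraction of the
#' fully equilibrated droplet. The expected final hydration of the
#' monoolein/water system is therefore
#' \deqn{w = 100 \cdot \phi V_s/d \,/\, (\phi V_s/d + M),}
#' strictly decreasing in the dilution factor `d`: stronger dilution of
#' the screen aliquot dehydrates the mesophase further.
#'
#' @inheritParams initial_hydration
#' @return An object of class `equilibrium_result` with fields
#'   `final_droplet_volume` (nl), `final_water_mass` (ug), `hydration_pct`
#'   and `rounded_hydration_pct` (integer percent, half up).
#' @examples
#' spec <- droplet_spec(450, 450, dilution_factor = 4)
#' expected_final_hydration(spec, calibration_params(0.88), mo_mass = 132)
#' @export
expected_final_hydration <- function(spec, cal = calibration_params(),
                                     mo_mass) {
  stopifnot(inherits(spec, "droplet_spec"), inherits(cal, "calibration_params"))
  v_f <- equilibrium_droplet_volume(spec)
  w_f <- cal$phi * v_f
  h <- water_weight_fraction(meso_system(mo_mass, w_f))
  structure(list(final_droplet_volume = v_f,
                 final_water_mass = w_f,
                 hydration_pct = h,
                 rounded_hydration_pct = as.integer(round_half_up(h))),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_result> V_f = %.4g nl, water = %.4g ug, hydration = %.2f wt%% (~%d%%)\n",
    x$final_droplet_volume, x$final_water_mass, x$hydration_pct,
    x$rounded_hydration_pct))
  invisible(x)
}

# forward model used by the calibration: hydration as a function of phi
hydration_from_phi <- function(phi, dilution, screen_volume, mo_mass) {
  w <- phi * screen_volume / dilution
  100 * w / (w + mo_mass)
}

#' Calibrate the endpoint water density phi from published hydration levels
#'
#' Recovers the single constant `phi` behind reported "expected hydration
#' level" values: given pairs of (dilution factor, hydration wt percent)
#' for a fixed screen volume and monoolein mass, finds the `phi` that
#' minimizes the maximum absolute residual between the forward model of
#' [expected_final_hydration()] and the reported levels (minimax fit, so a
#' single rounded caption value cannot drag the constant). With a single
#' observation the closed-form inversion is used.
#'
#' @param observations A two-column data frame (or matrix) with columns
#'   `dilution` and `hydration` (wt percent), one row per reported level.
#' @param screen_volume Screen aliquot volume in nl.
#' @param mo_mass Monoolein mass in ug.
#' @param interval Search interval for `phi` in ug/nl.
#' @param step Grid resolution of the coarse search; the optimum is then
#'   refined to ~1e-6.
#' @return A list of class `phi_calibration`: `params` (a
#'   [calibration_params()] holding the fitted `phi`), `residuals` (data
#'   frame of observed, fitted and residual hydration per observation) and
#'   `max_residual` (percentage points).
#' @examples
#' obs <- data.frame(dilution = c(1, 2, 4, 7), hydration = c(75, 60, 43, 30))
#' fit <- calibrate_phi(obs, screen_volume = 450, mo_mass = 132)
#' fit$params$phi
#' @export
calibrate_phi <- function(observations, screen_volume, mo_mass,
                          interval = c(0.5, 1.1), step = 0.001) {
  obs <- as.data.frame(observations)
  if (ncol(obs) == 2L && !all(c("dilution", "hydration") %in% names(obs))) {
    names(obs) <- c("dilution", "hydration")
  }
  if (!all(c("dilution", "hydration") %in% names(obs))) {
    stop_invalid("observations must have columns 'dilution' and 'hydration'")
  }
  if (nrow(obs) < 1L) stop_invalid("at least one observation is required")
  if (any(obs$dilution < 1) || any(obs$hydration <= 0) ||
      any(obs$hydration >= 100)) {
    stop_invalid("observations must have dilution >= 1 and hydration in (0, 100)")
  }
  check_number(screen_volume, "screen_volume", lower = .Machine$double.xmin)
  check_number(mo_mass, "mo_mass", lower = .Machine$double.xmin)

  if (nrow(obs) > 1L && length(unique(obs$dilution)) < 2L) {
    stop_invalid(paste0(
      "under-determined calibration: %d observations but only one distinct ",
      "dilution factor"), nrow(obs))
  }

  if (nrow(obs) == 1L) {
    # closed form: W = w M / (100 - w), phi = W d / V_s
    w_mass <- obs$hydration * mo_mass / (100 - obs$hydration)
    phi <- w_mass * obs$dilution / screen_volume
  } else {
    objective <- function(phi) {
      max(abs(hydration_from_phi(phi, obs$dilution, screen_volume, mo_mass) -
                obs$hydration))
    }
    grid <- seq(interval[1], interval[2], by = step)
    best <- grid[which.min(vapply(grid, objective, numeric(1)))]
    opt <- stats::optimize(objective,
                           lower = max(interval[1], best - step),
                           upper = min(interval[2], best + step),
                           tol = 1e-8)
    phi <- opt$minimum
  }

  fitted <- hydration_from_phi(phi, obs$dilution, screen_volume, mo_mass)
  res <- data.frame(dilution = obs$dilution,
                    observed = obs$hydration,
                    fitted = fitted,
                    residual = fitted - obs$hydration)
  structure(list(params = calibration_params(phi = phi),
                 residuals = res,
                 max_residual = max(abs(res$residual))),
            class = "phi_calibration")
}

#' @export
print.phi_calibration <- function(x, ...) {
  cat(sprintf("<phi_calibration> phi = %.4f ug/nl, max |residual| = %.3f points\n",
              x$params$phi, x$max_residual))
  print(x$residuals, row.names = FALSE)
  invisible(x)
}
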