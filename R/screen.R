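#' A screening (precipitant) solution
#'
#' The reservoir-strength solution that both dehydrates the droplet
#' through the vapor phase and supplies the crystallization chemistry.
#' Additives (e.g. malonate alongside an ammonium sulfate precipitant) are
#' carried as a table of (name, concentration, unit); the volume-fraction
#' composition records how the solution was mixed and must sum to 1.
#'
#' @param precipitant Precipitant name.
#' @param conc Precipitant concentration in mol/l.
#' @param pH Optional pH.
#' @param additives Optional data frame with columns `name`, `conc`,
#'   `unit`.
#' @param fractions Named numeric vector of volume fractions summing to 1.
#' @return An object of class `screen_solution`.
#' @examples
#' screen_solution("ammonium sulfate", 3.4,
#'                 additives = data.frame(name = "sodium malonate",
#'                                        conc = 380, unit = "mM"))
#' @export
screen_solution <- function(precipitant, conc, pH = NA_real_,
                            additives = NULL, fractions = c(base = 1)) {
  if (!is.character(precipitant) || length(precipitant) != 1L) {
    stop_invalid("'precipitant' must be a single name")
  }
  check_number(conc, "conc", lower = 0)
  if (is.null(additives)) {
    additives <- data.frame(name = character(), conc = numeric(),
                            unit = character(), stringsAsFactors = FALSE)
  }
  if (!all(c("name", "conc", "unit") %in% names(additives))) {
    stop_invalid("'additives' needs columns name, conc, unit")
  }
  if (any(additives$conc < 0)) stop_invalid("additive concentrations must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_invalid("volume fractions must sum to 1 (got %g)", sum(fractions))
  }
  structure(list(precipitant = precipitant, conc = conc, pH = pH,
                 additives = additives[, c("name", "conc", "unit")],
                 fractions = fractions),
            class = "screen_solution")
}

#' @export
print.screen_solution <- function(x, ...) {
  add <- if (nrow(x$additives) > 0) {
    paste0(" + ", paste(sprintf("%g %s %s", x$additives$conc,
                                x$additives$unit, x$additives$name),
                        collapse = ", "))
  } else ""
  ph <- if (is.na(x$pH)) "" else sprintf(", pH %g", x$pH)
  cat(sprintf("<screen_solution> %g M %s%s%s\n", x$conc, x$precipitant, ph, add))
  invisible(x)
}

#' Build a pH x precipitant-concentration grid screen
#'
#' A uniform grid including both endpoints on each axis, in row-major
#' order (pH varies over rows, concentration over columns), matching how
#' grid screens are laid out on a plate. A classic example is a phosphate
#' grid from pH 4.5 to 8.5 and 0.5 to 4.0 M on one 96-well plate
#' (8 pH x 12 concentrations).
#'
#' @param pH_min,pH_max pH range (min < max).
#' @param conc_min,conc_max Precipitant concentration range in mol/l.
#' @param n_pH,n_conc Number of grid points per axis (>= 2; a single-point
#'   axis cannot include both distinct endpoints).
#' @param precipitant Precipitant name attached to every condition.
#' @param wells_per_plate Capacity per plate; a larger grid is split over
#'   consecutive plates (with a warning) via the `plate` attribute.
#' @return A list of [screen_solution()]s with attribute `plate` (plate
#'   index per condition).
#' @examples
#' g <- build_grid_screen(4.5, 8.5, 0.5, 4.0, n_pH = 8, n_conc = 12)
#' length(g)
#' @export
build_grid_screen <- function(pH_min, pH_max, conc_min, conc_max,
                              n_pH, n_conc,
                              precipitant = "sodium/potassium phosphate",
                              wells_per_plate = 96) {
  if (!(pH_min < pH_max) || !(conc_min < conc_max)) {
    stop_invalid("grid ranges must satisfy min < max on both axes")
  }
  if (n_pH < 2 || n_conc < 2) {
    stop_invalid("degenerate grid axis: need at least 2 points per axis to span a range")
  }
  n <- n_pH * n_conc
  if (n > wells_per_plate) {
    warning(sprintf("grid of %d conditions exceeds one %d-well plate; split over %d plates",
                    n, wells_per_plate, ceiling(n / wells_per_plate)),
            call. = FALSE)
  }
  pHs <- seq(pH_min, pH_max, length.out = n_pH)
  concs <- seq(conc_min, conc_max, length.out = n_conc)
  out <- vector("list", n)
  k <- 0L
  for (p in pHs) {
    for (cc in concs) {
      k <- k + 1L
      out[[k]] <- screen_solution(precipitant, conc = cc, pH = p)
    }
  }
  attr(out, "plate") <- (seq_len(n) - 1L) %/% wells_per_plate + 1L
  out
}

#' Mix an additive into a screening solution
#'
#' Replaces a volume fraction of the base solution by an additive stock
#' ("diluting the precipitant with additive"), e.g. 10 percent (v/v)
#' additive content: 90 parts base plus 10 parts additive. The base
#' precipitant (and any pre-existing additives) are scaled by
#' `1 - fraction`; the additive enters at `fraction` times its stock
#' concentration. Volume fractions are updated to keep summing to 1.
#'
#' @param base A [screen_solution()].
#' @param name Additive name.
#' @param stock_conc Additive stock concentration.
#' @param unit Unit of the additive concentration (e.g. `"mM"`,
#'   `"% (v/v)"`).
#' @param fraction Final volume fraction of additive stock in the mix
#'   (default 0.10); must be in `[0, 1)`. `0` returns the base unchanged.
#' @return A new [screen_solution()].
#' @examples
#' base <- screen_solution("ammonium sulfate", 4.0)
#' with_additive(base, "sodium malonate", stock_conc = 1000, unit = "mM")
#' @export
with_additive <- function(base, name, stock_conc, unit = "mM",
                          fraction = 0.10) {
  stopifnot(inherits(base, "screen_solution"))
  check_number(fraction, "fraction", lower = 0)
  if (fraction >= 1) stop_invalid("additive fraction must be < 1")
  if (fraction == 0) return(base)
  adds <- base$additives
  adds$conc <- adds$conc * (1 - fraction)
  adds <- rbind(adds, data.frame(name = name, conc = stock_conc * fraction,
                                 unit = unit, stringsAsFactors = FALSE))
  fr <- c(base$fractions * (1 - fraction), fraction)
  names(fr) <- c(names(base$fractions), name)
  screen_solution(base$precipitant, base$conc * (1 - fraction), pH = base$pH,
                  additives = adds, fractions = fr)
}

#' Dilute a screening solution
#'
#' Divides every solute concentration (precipitant and additives) by the
#' dilution factor, e.g. a 1:2 dilution of a 3.4 M ammonium sulfate /
#' 380 mM malonate reservoir gives 1.7 M / 190 mM.
#'
#' @param reservoir A [screen_solution()].
#' @param d Dilution factor `>= 1`; `1` is the identity.
#' @return A new [screen_solution()].
#' @export
dilute_screen <- function(reservoir, d) {
  stopifnot(inherits(reservoir, "screen_solution"))
  check_number(d, "d", lower = 1)
  adds <- reservoir$additives
  adds$conc <- adds$conc / d
  screen_solution(reservoir$precipitant, reservoir$conc / d,
                  pH = reservoir$pH, additives = adds,
                  fractions = reservoir$fractions)
}

# supported precoated-plate formats; reservoir for the 29 ug plate is not
# separately specified by the protocol and defaults to the 132 ug value
plate_formats <- list(
  mo132 = list(mo_mass = 132, protein_volume = 450, screen_volume = 450,
               reservoir_volume_ul = 75),
  mo29 = list(mo_mass = 29, protein_volume = 100, screen_volume = 100,
              reservoir_volume_ul = 75),
  foil100 = list(mo_mass = 100, protein_volume = 300, screen_volume = 300,
                 reservoir_volume_ul = 50)
)

#' Precoated plate format defaults
#'
#' Volume and lipid-mass defaults per supported plate format:
#' `mo132` (132 ug monoolein, 450 + 450 nl, 75 ul reservoir),
#' `mo29` (29 ug, 100 + 100 nl, 75 ul reservoir) and `foil100`
#' (hanging-drop crystallization foil, 100 ug, 300 + 300 nl, 50 ul
#' reservoir).
#'
#' @param format Format name.
#' @return A list with `mo_mass` (ug), `protein_volume`, `screen_volume`
#'   (nl) and `reservoir_volume_ul`.
#' @export
plate_format <- function(format = c("mo132", "mo29", "foil100")) {
  format <- match.arg(format)
  plate_formats[[format]]
}

well_ids_96 <- function(n = 96) {
  stopifnot(n <= 96)
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))[seq_len(n)]
}

#' Plan a 96-well crystallization plate
#'
#' Lays out one condition per well (row-major, A1..H12): each condition is
#' a screening solution combined with a dilution factor from the scheme.
#' Every well carries the format's volumes, the protein mass it consumes
#' (volume x concentration), the predicted equilibrium hydration and the
#' targeted mesophase, plus the protocol timeline (3-h swelling before the
#' screen aliquot and reservoir are dispensed, then sealed incubation at
#' 22 degrees C with weekly inspection).
#'
#' @param protein_conc Protein concentration in ug/ul.
#' @param screens A list of [screen_solution()]s (or a single one).
#' @param format Plate format name, see [plate_format()].
#' @param dilutions Numeric vector of dilution factors; conditions are the
#'   cross of screens and dilutions (screens vary fastest).
#' @param cal A [calibration_params()].
#' @param map A [phase_map()].
#' @param metadata Named list stored with the plate (protein name,
#'   operator, date, ...).
#' @return An object of class `plate_layout` with fields `format`,
#'   `format_spec`, `protein_conc`, `wells` (data frame), `screens`,
#'   `timeline` and `metadata`.
#' @examples
#' g <- build_grid_screen(4.5, 8.5, 0.5, 4.0, 8, 12)
#' plate <- plan_plate(16, g, format = "mo132", dilutions = 4)
#' head(plate$wells[, c("well", "pH", "conc", "predicted_hydration", "phase")])
#' @export
plan_plate <- function(protein_conc, screens, format = "mo132",
                       dilutions = 1, cal = calibration_params(),
                       map = default_phase_map(), metadata = list()) {
  check_number(protein_conc, "protein_conc", lower = .Machine$double.xmin)
  if (inherits(screens, "screen_solution")) screens <- list(screens)
  if (!all(vapply(screens, inherits, logical(1), "screen_solution"))) {
    stop_invalid("'screens' must be screen_solution objects")
  }
  if (any(dilutions < 1)) stop_invalid("dilution factors must be >= 1")
  fmt <- plate_format(format)

  n_scr <- length(screens)
  n <- n_scr * length(dilutions)
  if (n > 96) {
    stop_invalid("%d conditions do not fit one 96-well plate; split the screen first", n)
  }

  if (n == 0L) {
    wells <- data.frame(well = character(), screen_index = integer(),
                        precipitant = character(), conc = numeric(),
                        pH = numeric(), dilution_factor = numeric(),
                        protein_volume = numeric(), screen_volume = numeric(),
                        reservoir_volume_ul = numeric(), mo_mass = numeric(),
                        protein_mass = numeric(), predicted_hydration = numeric(),
                        rounded_hydration = integer(), phase = character(),
                        boundary = character(), stringsAsFactors = FALSE)
  } else {
    idx_scr <- rep(seq_len(n_scr), times = length(dilutions))
    idx_dil <- rep(seq_along(dilutions), each = n_scr)
    hyd <- vapply(dilutions, function(d) {
      expected_final_hydration(
        droplet_spec(fmt$protein_volume, fmt$screen_volume, d),
        cal, fmt$mo_mass)$hydration_pct
    }, numeric(1))
    cls <- classify_phase(hyd, map)
    wells <- data.frame(
      well = well_ids_96(n),
      screen_index = idx_scr,
      precipitant = vapply(screens[idx_scr], `[[`, character(1), "precipitant"),
      conc = vapply(screens[idx_scr], `[[`, numeric(1), "conc"),
      pH = vapply(screens[idx_scr], `[[`, numeric(1), "pH"),
      dilution_factor = dilutions[idx_dil],
      protein_volume = fmt$protein_volume,
      screen_volume = fmt$screen_volume,
      reservoir_volume_ul = fmt$reservoir_volume_ul,
      mo_mass = fmt$mo_mass,
      protein_mass = protein_conc * fmt$protein_volume / 1000,
      predicted_hydration = hyd[idx_dil],
      rounded_hydration = as.integer(round_half_up(hyd[idx_dil])),
      phase = cls$phase[idx_dil],
      boundary = cls$boundary[idx_dil],
      stringsAsFactors = FALSE)
  }

  layout <- structure(list(
    format = format,
    format_spec = fmt,
    protein_conc = protein_conc,
    wells = wells,
    screens = screens,
    cal = cal,
    timeline = list(swelling_hours = 3, temperature_C = 22,
                    inspection = "weekly"),
    metadata = metadata), class = "plate_layout")
  validate_plate_layout(layout)
  layout
}

#' Validate a plate layout
#'
#' Checks SBS 96-well geometry (well ids A1-H12, unique), that per-well
#' volumes and monoolein masses match the plate format, and that predicted
#' hydration values are consistent with a direct evaluation of the
#' equilibration model. Errors list the offending wells.
#'
#' @param layout A `plate_layout`.
#' @return `layout`, invisibly, if valid.
#' @export
validate_plate_layout <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells
  fmt <- layout$format_spec
  valid_ids <- well_ids_96(96)
  bad <- w$well[!(w$well %in% valid_ids)]
  if (length(bad) > 0) {
    stop_invalid("invalid well id(s): %s", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(w$well)) {
    stop_invalid("duplicated well id(s): %s",
                 paste(unique(w$well[duplicated(w$well)]), collapse = ", "))
  }
  off <- w$well[w$protein_volume != fmt$protein_volume |
                  w$screen_volume != fmt$screen_volume |
                  w$mo_mass != fmt$mo_mass]
  if (length(off) > 0) {
    stop_invalid("wells with volumes/mass not matching format '%s': %s",
                 layout$format, paste(off, collapse = ", "))
  }
  if (nrow(w) > 0) {
    redo <- vapply(w$dilution_factor, function(d) {
      expected_final_hydration(
        droplet_spec(fmt$protein_volume, fmt$screen_volume, d),
        layout$cal, fmt$mo_mass)$hydration_pct
    }, numeric(1))
    if (any(abs(redo - w$predicted_hydration) > 1e-9)) {
      stop_invalid("predicted hydration inconsistent with the equilibration model")
    }
  }
  invisible(layout)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s format: %d condition(s), %g ug/ul protein (%.2g ug/well)\n",
              x$format, nrow(x$wells), x$protein_conc,
              x$protein_conc * x$format_spec$protein_volume / 1000))
  if (nrow(x$wells) > 0) {
    tab <- unique(x$wells[, c("dilution_factor", "rounded_hydration", "phase")])
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  d = %-5.3g -> %d%% hydration, %s\n",
                  tab$dilution_factor[i], tab$rounded_hydration[i], tab$phase[i]))
    }
  }
  invisible(x)
}

#' Total protein consumption of a plate
#'
#' @param layout A `plate_layout`.
#' @return Total protein mass in ug (sum over wells of volume x
#'   concentration).
#' @export
protein_consumption <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  sum(layout$wells$protein_mass)
}
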