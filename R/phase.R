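#' Monoolein/water mesophase map
#'
#' An ordered partition of the hydration axis (0-100 wt percent water)
#' into mesophase intervals at a fixed temperature. With increasing water
#' content monoolein passes through the crystalline lamellar phase (Lc),
#' the fluid lamellar phase (L-alpha), the bicontinuous cubic phases Ia3d
#' and Pn3m, and finally Pn3m in equilibrium with excess aqueous phase.
#' Interval `i` covers hydration values in `[bounds[i-1], bounds[i])`,
#' with the first interval starting at 0 and the last ending at 100.
#'
#' The default boundary positions at 22 degrees C are calibrated so that
#' the hydration levels the standard dilution series reaches classify as
#' observed in practice: 60 and 75 percent as excess-water conditions,
#' 43 percent as cubic (Pn3m), and 30 percent as the cubic/lamellar
#' boundary condition. They are configuration values, not constants: in a
#' real experiment protein, detergent, salt and additives shift the
#' boundaries, so the true phase diagram of the system is unknown and the
#' map is only a targeting aid.
#'
#' @param bounds Strictly increasing hydration values in (0, 100), wt
#'   percent, separating consecutive phases.
#' @param labels Phase labels, one more than `bounds`, in increasing order
#'   of water content.
#' @param boundary_names Human-readable names of the boundaries, one per
#'   element of `bounds`; used for boundary tagging by [classify_phase()].
#' @param temperature_C Temperature tag of the isotherm, degrees C.
#' @return An object of class `phase_map`.
#' @examples
#' default_phase_map()
#' @export
phase_map <- function(bounds = c(4, 30, 37, 44),
                      labels = c("Lc", "L_alpha", "Ia3d", "Pn3m",
                                 "Pn3m_excess_water"),
                      boundary_names = c("Lc/L_alpha", "cubic/lamellar",
                                         "Ia3d/Pn3m", "cubic/excess water"),
                      temperature_C = 22) {
  if (length(labels) != length(bounds) + 1L) {
    stop_invalid("need exactly one more label (%d) than bounds (%d)",
                 length(labels), length(bounds))
  }
  if (length(boundary_names) != length(bounds)) {
    stop_invalid("need one boundary name per bound")
  }
  if (any(diff(bounds) <= 0)) {
    stop_invalid("phase boundaries must be strictly increasing")
  }
  if (any(bounds <= 0) || any(bounds >= 100)) {
    stop_invalid("phase boundaries must lie strictly inside (0, 100) wt%%")
  }
  if (anyDuplicated(labels)) stop_invalid("phase labels must be unique")
  structure(list(bounds = as.numeric(bounds),
                 labels = as.character(labels),
                 boundary_names = as.character(boundary_names),
                 temperature_C = temperature_C),
            class = "phase_map")
}

#' @rdname phase_map
#' @export
default_phase_map <- function() phase_map()

#' @export
print.phase_map <- function(x, ...) {
  lo <- c(0, x$bounds)
  hi <- c(x$bounds, 100)
  cat(sprintf("<phase_map> monoolein/water at %g C\n", x$temperature_C))
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %5.1f - %5.1f wt%%  %s\n", lo[i], hi[i], x$labels[i]))
  }
  invisible(x)
}

# JSON round trip so a custom map can live in a config file
#' Read or write a phase map as JSON
#'
#' @param map A [phase_map()].
#' @param path File path.
#' @return `read_phase_map()` returns a [phase_map()];
#'   `write_phase_map()` returns `path` invisibly.
#' @export
write_phase_map <- function(map, path) {
  stopifnot(inherits(map, "phase_map"))
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_map
#' @export
read_phase_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phase_map(bounds = x$bounds, labels = x$labels,
            boundary_names = x$boundary_names,
            temperature_C = x$temperature_C)
}

#' Classify hydration levels into mesophases
#'
#' Looks up which interval of the phase map contains each hydration value.
#' A value within `boundary_tol` percentage points of a phase boundary
#' additionally carries the boundary's name as a tag: such conditions sit
#' on a transition (e.g. the 30 wt percent condition of the standard 1:7
#' dilution is a cubic/lamellar boundary condition) and in practice show
#' coexisting phases.
#'
#' @param hydration Numeric vector of hydration levels, wt percent in
#'   `[0, 100]`.
#' @param map A [phase_map()].
#' @param boundary_tol Half-width of the boundary band in percentage
#'   points (default 1.5).
#' @return A data frame with one row per input value and columns
#'   `hydration`, `phase` and `boundary` (`NA` when not near a boundary).
#' @examples
#' classify_phase(c(30, 43, 60, 75))
#' @export
classify_phase <- function(hydration, map = default_phase_map(),
                           boundary_tol = 1.5) {
  stopifnot(inherits(map, "phase_map"))
  if (!is.numeric(hydration) || any(is.na(hydration))) {
    stop_invalid("'hydration' must be numeric with no missing values")
  }
  if (any(hydration < 0 | hydration > 100)) {
    stop_invalid("hydration must lie in [0, 100] wt%%")
  }
  idx <- findInterval(hydration, map$bounds) + 1L
  near <- vapply(hydration, function(h) {
    d <- abs(map$bounds - h)
    if (min(d) <= boundary_tol) which.min(d) else NA_integer_
  }, integer(1))
  data.frame(hydration = hydration,
             phase = map$labels[idx],
             boundary = ifelse(is.na(near), NA_character_,
                               map$boundary_names[near]),
             stringsAsFactors = FALSE)
}

# highest hydration reachable with d = 1 for a given screen volume / MO mass
max_reachable_hydration <- function(screen_volume, mo_mass, cal) {
  hydration_from_phi(cal$phi, 1, screen_volume, mo_mass)
}

#' Screen dilution factor that targets a hydration level
#'
#' Inverts the endpoint mass balance of [expected_final_hydration()]:
#' \deqn{d = \phi V_s (100 - w) / (w M).}
#' Because the added screen aliquot can at most be undiluted (`d = 1`),
#' hydration levels above the `d = 1` endpoint are unreachable and raise
#' an error stating the reachable range.
#'
#' @param target Target hydration, wt percent.
#' @param screen_volume Screen aliquot volume in nl.
#' @param mo_mass Monoolein mass in ug.
#' @param cal A [calibration_params()].
#' @return The required dilution factor (`>= 1`).
#' @examples
#' dilution_for_hydration(43, 450, 132) # ~3.98, i.e. use a ~1:4 dilution
#' @export
dilution_for_hydration <- function(target, screen_volume, mo_mass,
                                   cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"))
  check_number(target, "target", lower = .Machine$double.xmin, upper = 100)
  w_max <- max_reachable_hydration(screen_volume, mo_mass, cal)
  d <- cal$phi * screen_volume * (100 - target) / (target * mo_mass)
  if (d < 1) {
    stop_invalid(paste0(
      "target hydration %.1f%% is unreachable: with %g nl screen on %g ug ",
      "monoolein the reachable range is (0, %.1f%%]"),
      target, screen_volume, mo_mass, w_max)
  }
  d
}

#' Recommend a dilution series targeting a set of mesophases
#'
#' For each requested phase (a label of the map, or the name of one of its
#' boundaries) picks a target hydration - the midpoint of the phase
#' interval, or the boundary hydration itself - and inverts the hydration
#' model to obtain the screen dilution factor. Dilutions below 1 (targets
#' wetter than the undiluted endpoint) are clamped to the undiluted
#' experiment. Optionally the exact factors are snapped to the practical
#' grid `{1, 2, 4, 7}` a pipetting robot would actually use.
#'
#' Phases whose hydration interval lies entirely above the reachable range
#' are skipped with a warning.
#'
#' @param phases Character vector of phase labels and/or boundary names.
#' @param screen_volume Screen aliquot volume in nl.
#' @param mo_mass Monoolein mass in ug.
#' @param cal A [calibration_params()].
#' @param map A [phase_map()].
#' @param snap If `TRUE`, snap each dilution to the nearest value of
#'   `snap_grid`.
#' @param snap_grid Practical dilution factors available on the deck.
#' @return Data frame with columns `phase`, `target_hydration`,
#'   `dilution_factor` and `predicted_hydration` (forward model at the
#'   returned factor).
#' @examples
#' dilution_series_for_phases(
#'   c("Pn3m_excess_water", "Pn3m", "cubic/lamellar"), 450, 132,
#'   snap = TRUE)
#' @export
dilution_series_for_phases <- function(phases, screen_volume, mo_mass,
                                       cal = calibration_params(),
                                       map = default_phase_map(),
                                       snap = FALSE,
                                       snap_grid = c(1, 2, 4, 7)) {
  stopifnot(inherits(cal, "calibration_params"), inherits(map, "phase_map"))
  if (length(phases) == 0L) stop_invalid("'phases' must be non-empty")
  lo <- c(0, map$bounds)
  hi <- c(map$bounds, 100)
  w_max <- max_reachable_hydration(screen_volume, mo_mass, cal)

  rows <- lapply(phases, function(ph) {
    if (ph %in% map$labels) {
      i <- match(ph, map$labels)
      if (lo[i] >= w_max) {
        warning(sprintf(
          "phase '%s' (%g-%g wt%%) is unreachable with %g nl screen on %g ug MO; skipped",
          ph, lo[i], hi[i], screen_volume, mo_mass), call. = FALSE)
        return(NULL)
      }
      target <- (lo[i] + hi[i]) / 2
    } else if (ph %in% map$boundary_names) {
      target <- map$bounds[match(ph, map$boundary_names)]
      if (target >= w_max) {
        warning(sprintf("boundary '%s' (%g wt%%) is unreachable; skipped",
                        ph, target), call. = FALSE)
        return(NULL)
      }
    } else {
      stop_invalid("unknown phase or boundary '%s'", ph)
    }
    d <- cal$phi * screen_volume * (100 - target) / (target * mo_mass)
    d <- max(d, 1)  # wetter targets than the undiluted endpoint: run undiluted
    if (snap) d <- snap_grid[which.min(abs(snap_grid - d))]
    data.frame(phase = ph, target_hydration = target, dilution_factor = d,
               predicted_hydration = hydration_from_phi(
                 cal$phi, d, screen_volume, mo_mass),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop_invalid("no requested phase is reachable with the given geometry")
  }
  do.call(rbind, rows)
}
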