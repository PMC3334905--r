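# worklist CSV dialect: comma-separated, header row, UTF-8, volumes as
# integer nl; lowest common denominator for robot control software

encode_additives <- function(additives) {
  if (nrow(additives) == 0) return("")
  paste(sprintf("%s=%g %s", additives$name, additives$conc, additives$unit),
        collapse = "; ")
}

encode_fractions <- function(fractions) {
  paste(sprintf("%s=%.15g", names(fractions), fractions), collapse = "; ")
}

decode_fractions <- function(s) {
  parts <- strsplit(s, "; ", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(as.numeric(vapply(kv, `[[`, character(1), 2)),
           vapply(kv, `[[`, character(1), 1))
}

decode_additives <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(name = character(), conc = numeric(),
                      unit = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(s, "; ", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*)=([0-9.eE+-]+) (.*)$", parts))
  if (any(vapply(m, length, integer(1)) != 4L)) {
    stop_invalid("cannot parse additive field '%s'", s)
  }
  data.frame(name = vapply(m, `[[`, character(1), 2),
             conc = as.numeric(vapply(m, `[[`, character(1), 3)),
             unit = vapply(m, `[[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Export a plate layout as a robot worklist
#'
#' One dispensing step per row, in protocol order: first the protein
#' solution into every experiment well (after which the plate is sealed
#' for the 3-h swelling phase), then the diluted screen aliquot into every
#' experiment well, then the undiluted screening solution into every
#' reservoir well. Volumes are integer nanoliters. Each row also carries
#' the condition descriptors (format, concentrations, dilution factor) so
#' that [import_worklist()] is the exact inverse.
#'
#' @param layout A `plate_layout` from [plan_plate()].
#' @return A data frame with columns `step_order`, `step`, `source`,
#'   `destination`, `volume_nl` plus condition descriptor columns.
#' @examples
#' plate <- plan_plate(16, screen_solution("ammonium sulfate", 3.4),
#'                     dilutions = 2)
#' export_worklist(plate)
#' @export
export_worklist <- function(layout) {
  validate_plate_layout(layout)
  w <- layout$wells
  adds <- vapply(layout$screens, function(s) encode_additives(s$additives),
                 character(1))
  frs <- vapply(layout$screens, function(s) encode_fractions(s$fractions),
                character(1))
  one <- function(step_order, step, source, destination, volume_nl) {
    data.frame(step_order = step_order, step = step, source = source,
               destination = destination,
               volume_nl = as.integer(round(volume_nl)),
               format = layout$format,
               protein_conc_ug_ul = layout$protein_conc,
               phi = layout$cal$phi,
               screen_index = w$screen_index,
               precipitant = w$precipitant,
               conc_M = w$conc,
               pH = w$pH,
               additives = adds[w$screen_index],
               fractions = frs[w$screen_index],
               dilution_factor = w$dilution_factor,
               stringsAsFactors = FALSE)
  }
  if (nrow(w) == 0) {
    return(one(integer(), character(), character(), character(), integer()))
  }
  rbind(
    one(1L, "protein", "protein_sample", w$well, w$protein_volume),
    one(2L, "screen_diluted",
        sprintf("screen%02d_d%g", w$screen_index, w$dilution_factor),
        w$well, w$screen_volume),
    one(3L, "reservoir", sprintf("screen%02d_undiluted", w$screen_index),
        paste0("R", w$well), w$reservoir_volume_ul * 1000)
  )
}

#' Rebuild a plate layout from a worklist
#'
#' Exact inverse of [export_worklist()]: reconstructs the screening
#' solutions, dilution scheme and plate format from the condition
#' descriptor columns and re-derives the predicted hydration and phase.
#'
#' @param records Worklist data frame as produced by [export_worklist()]
#'   or [read_worklist()].
#' @param map A [phase_map()] for re-deriving phase predictions.
#' @return A `plate_layout`.
#' @export
import_worklist <- function(records, map = default_phase_map()) {
  need <- c("step_order", "step", "source", "destination", "volume_nl",
            "format", "protein_conc_ug_ul", "phi", "screen_index",
            "precipitant", "conc_M", "pH", "additives", "fractions",
            "dilution_factor")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop_invalid("worklist is missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  scr_rows <- records[records$step == "screen_diluted", , drop = FALSE]
  if (nrow(scr_rows) == 0) {
    fmt <- if (nrow(records) > 0) records$format[1] else "mo132"
    pc <- if (nrow(records) > 0) records$protein_conc_ug_ul[1] else 1
    return(plan_plate(pc, list(), format = fmt, map = map))
  }
  fmt <- unique(scr_rows$format)
  if (length(fmt) != 1L) stop_invalid("worklist mixes plate formats")
  # reconstruct screens in index order (reservoir-strength concentrations
  # are stored, so no un-dilution is needed)
  scr_idx <- sort(unique(scr_rows$screen_index))
  if (!identical(scr_idx, seq_along(scr_idx))) {
    stop_invalid("screen indices in worklist are not contiguous from 1")
  }
  screens <- lapply(scr_idx, function(i) {
    r <- scr_rows[scr_rows$screen_index == i, , drop = FALSE][1, ]
    adds <- decode_additives(r$additives)
    screen_solution(r$precipitant, r$conc_M, pH = r$pH, additives = adds,
                    fractions = decode_fractions(r$fractions))
  })
  # condition order on the plate is destination-well order of screen rows
  ids <- well_ids_96(96)
  scr_rows <- scr_rows[order(match(scr_rows$destination, ids)), , drop = FALSE]
  n_scr <- length(screens)
  dilutions <- unique(scr_rows$dilution_factor)
  expect_scr <- rep(seq_len(n_scr), times = length(dilutions))
  expect_dil <- rep(dilutions, each = n_scr)
  if (!identical(as.integer(scr_rows$screen_index), as.integer(expect_scr)) ||
      !isTRUE(all.equal(scr_rows$dilution_factor, expect_dil))) {
    stop_invalid("worklist conditions are not a screens-by-dilutions cross in plate order")
  }
  plan_plate(scr_rows$protein_conc_ug_ul[1], screens, format = fmt,
             dilutions = dilutions,
             cal = calibration_params(phi = scr_rows$phi[1]), map = map)
}

#' Read or write a worklist CSV
#'
#' @param worklist Worklist data frame from [export_worklist()].
#' @param path CSV file path.
#' @return `read_worklist()` returns the worklist data frame;
#'   `write_worklist()` returns `path` invisibly.
#' @export
write_worklist <- function(worklist, path) {
  write.csv(worklist, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_worklist
#' @export
read_worklist <- function(path) {
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE,
             colClasses = c(additives = "character",
                            fractions = "character", pH = "numeric")),
    error = function(e) stop_invalid("malformed worklist CSV %s: %s",
                                     path, conditionMessage(e)))
  vol <- suppressWarnings(as.numeric(df$volume_nl))
  if (anyNA(vol)) {
    stop_invalid("malformed worklist CSV %s: non-numeric volume at row(s) %s",
                 path, paste(which(is.na(vol)), collapse = ", "))
  }
  df$volume_nl <- as.integer(vol)
  df$additives[is.na(df$additives)] <- ""
  df
}
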