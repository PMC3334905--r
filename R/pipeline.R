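# configuration-driven end-to-end run: plan -> predict -> (optional) K
# estimation -> JSON report

#' Read and validate a run configuration
#'
#' The configuration is a JSON object (schema shipped at
#' `inst/schema/run-config.schema.json`) with fields:
#' \describe{
#'   \item{plate_format}{`"mo132"`, `"mo29"` or `"foil100"`.}
#'   \item{protein}{Object with `conc_ug_ul` (> 0) and optional `name`.}
#'   \item{screen}{Either `grid` (with `pH_min`, `pH_max`, `conc_min`,
#'     `conc_max`, `n_pH`, `n_conc`, optional `precipitant`) or
#'     `conditions` (array of objects with `precipitant`, `conc`,
#'     optional `pH`).}
#'   \item{dilutions}{Array of dilution factors `>= 1`; or instead}
#'   \item{target_hydrations}{Array of target hydration levels (wt
#'     percent) inverted through the hydration model.}
#'   \item{phi}{Optional calibration constant, default 0.88.}
#'   \item{phase_map}{Optional path to a phase-map JSON file.}
#'   \item{assay_csv}{Optional path to a partitioning assay CSV; triggers
#'     K estimation.}
#'   \item{seed}{Integer seed for the bootstrap.}
#' }
#'
#' @param path Path to the JSON configuration.
#' @return The validated configuration list, classed `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop_invalid("config must be a JSON object")
  fail <- function(field, why) {
    stop_invalid("invalid config: field '%s' %s", field, why)
  }
  if (is.null(config$plate_format) ||
      !config$plate_format %in% names(plate_formats)) {
    fail("plate_format", sprintf("must be one of %s",
                                 paste(names(plate_formats), collapse = ", ")))
  }
  if (is.null(config$protein$conc_ug_ul) ||
      !is.numeric(config$protein$conc_ug_ul) ||
      config$protein$conc_ug_ul <= 0) {
    fail("protein.conc_ug_ul", "must be a positive number")
  }
  if (is.null(config$screen$grid) && is.null(config$screen$conditions)) {
    fail("screen", "must contain 'grid' or 'conditions'")
  }
  if (!is.null(config$screen$grid)) {
    need <- c("pH_min", "pH_max", "conc_min", "conc_max", "n_pH", "n_conc")
    miss <- setdiff(need, names(config$screen$grid))
    if (length(miss) > 0) {
      fail("screen.grid", paste("is missing", paste(miss, collapse = ", ")))
    }
  }
  if (is.null(config$dilutions) && is.null(config$target_hydrations)) {
    fail("dilutions", "or 'target_hydrations' must be given")
  }
  if (!is.null(config$dilutions) &&
      (!is.numeric(config$dilutions) || any(config$dilutions < 1))) {
    fail("dilutions", "must be numbers >= 1")
  }
  if (!is.null(config$target_hydrations) &&
      (!is.numeric(config$target_hydrations) ||
         any(config$target_hydrations <= 0 | config$target_hydrations >= 100))) {
    fail("target_hydrations", "must be numbers in (0, 100)")
  }
  if (!is.null(config$phi)) check_number(config$phi, "phi", lower = 1e-6, upper = 1.1)
  if (is.null(config$seed)) config$seed <- 1L
  structure(config, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full planning pipeline from a configuration
#'
#' Executes the standard workflow: build the screening solutions, convert
#' hydration targets to dilution factors if requested, plan the plate
#' (with per-well hydration and phase predictions), and - when an assay
#' CSV is configured - estimate the apparent partitioning constant with a
#' bootstrap interval. Any stage error is re-raised with the stage name
#' and offending input. The report is fully determined by the
#' configuration and seed.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list to be
#'   validated.
#' @return A list of class `run_report` with elements `config_summary`,
#'   `plate` (the `plate_layout`), `wells` (prediction table),
#'   `k_estimate` (or `NULL`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  fmt <- plate_format(config$plate_format)
  cal <- calibration_params(phi = if (is.null(config$phi)) 0.88 else config$phi)
  map <- if (!is.null(config$phase_map)) {
    stage("phase-map", read_phase_map(config$phase_map))
  } else default_phase_map()

  screens <- stage("screens", {
    if (!is.null(config$screen$grid)) {
      g <- config$screen$grid
      do.call(build_grid_screen,
              c(g[c("pH_min", "pH_max", "conc_min", "conc_max",
                    "n_pH", "n_conc")],
                if (!is.null(g$precipitant)) list(precipitant = g$precipitant)))
    } else {
      conds <- config$screen$conditions
      if (is.data.frame(conds)) conds <- split(conds, seq_len(nrow(conds)))
      lapply(conds, function(x) {
        screen_solution(x$precipitant, x$conc,
                        pH = if (is.null(x$pH) || is.na(x$pH)) NA_real_ else x$pH)
      })
    }
  })

  dilutions <- if (!is.null(config$dilutions)) config$dilutions else {
    stage("hydration-targets", {
      vapply(seq_along(config$target_hydrations), function(i) {
        tryCatch(
          dilution_for_hydration(config$target_hydrations[i],
                                 fmt$screen_volume, fmt$mo_mass, cal),
          error = function(e) stop_invalid(
            "target %d (%.4g%%, wells %s): %s", i, config$target_hydrations[i],
            paste(range(well_ids_96(96)[seq_along(screens) +
                                          (i - 1L) * length(screens)]),
                  collapse = "-"),
            conditionMessage(e)))
      }, numeric(1))
    })
  }

  plate <- stage("plan", plan_plate(config$protein$conc_ug_ul, screens,
                                    format = config$plate_format,
                                    dilutions = dilutions, cal = cal,
                                    map = map,
                                    metadata = list(protein = config$protein$name)))

  k_est <- NULL
  if (!is.null(config$assay_csv)) {
    k_est <- stage("estimate-k", {
      assay <- read_assay_csv(config$assay_csv)
      est <- suppressWarnings(estimate_K(assay))
      ci <- if (nrow(assay) >= 3) {
        bootstrap_K_interval(assay, seed = config$seed)
      } else NULL
      list(K = est$K, n_replicates = est$n,
           ci_lower = if (is.null(ci)) NA_real_ else ci$lower,
           ci_upper = if (is.null(ci)) NA_real_ else ci$upper,
           replicates = est$replicates)
    })
  }

  structure(list(
    config_summary = list(plate_format = config$plate_format,
                          protein_conc_ug_ul = config$protein$conc_ug_ul,
                          phi = cal$phi,
                          n_conditions = nrow(plate$wells),
                          protein_consumed_ug = protein_consumption(plate),
                          seed = config$seed),
    plate = plate,
    wells = plate$wells,
    k_estimate = k_est), class = "run_report")
}

#' Write a pipeline report as JSON
#'
#' Serializes the prediction table and summary (not the full layout
#' object). The output contains no timestamp, so identical configurations
#' and seeds give byte-identical reports.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(config = report$config_summary,
              wells = report$wells,
              k_estimate = report$k_estimate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
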