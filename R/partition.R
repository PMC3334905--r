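#' Nernst partitioning parameters
#'
#' The partitioning constant `K = C_lip / C_aq` is the ratio of protein
#' concentration (molality) in the lipidic phase to that in the aqueous
#' phase, for a protein assumed monomeric in both phases. `C_lip` is taken
#' per kg of monoolein and `C_aq` per kg of total water - all water,
#' including the water inside the mesophase, counts towards the aqueous
#' pool. High `K` means the protein is drawn into the lipidic phase.
#'
#' @param K Dimensionless partitioning constant, `K >= 0` (`Inf` allowed
#'   as the complete-incorporation limit).
#' @return An object of class `partition_params`.
#' @export
partition_params <- function(K) {
  check_number(K, "K", lower = 0, allow_inf = TRUE)
  structure(list(K = K), class = "partition_params")
}

as_partition_params <- function(x) {
  if (inherits(x, "partition_params")) x else partition_params(x)
}

#' Fraction of protein incorporated into the lipidic phase
#'
#' With `C_lip = K * C_aq` and masses `M` of monoolein and `W` of total
#' water, conservation of protein gives the incorporated fraction
#' \deqn{f = K M / (K M + W).}
#' `f` increases with `K` and with dehydration (decreasing `W`): removing
#' water by vapor diffusion forces the protein into the mesophase, and in
#' the limit of total disappearance of the aqueous phase all protein is
#' incorporated.
#'
#' @param params A [partition_params()] (or a bare numeric `K`).
#' @param system A [meso_system()] giving `M` and the total water `W`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' # 40 wt% water on the standard 132 ug coating
#' fraction_incorporated(partition_params(25), meso_system(132, 88))
#' @export
fraction_incorporated <- function(params, system) {
  params <- as_partition_params(params)
  stopifnot(inherits(system, "meso_system"))
  K <- params$K
  if (K == 0) return(0)
  if (is.infinite(K)) return(1)
  if (system$water_mass == 0) return(1)
  K * system$mo_mass / (K * system$mo_mass + system$water_mass)
}

#' Remaining aqueous protein concentration relative to the sample
#'
#' The protein left in the aqueous pool after equilibration, expressed as
#' the ratio of its concentration (over the final droplet volume,
#' including the water content of the mesophase) to the concentration of
#' the applied protein sample:
#' \deqn{C_{sup}/C_0 = (1 - f)\, V_p\, d / V_s.}
#' For `K = 0` (no incorporation) and equal protein and screen volumes the
#' ratio equals the dilution factor `d` - the ideally-diluted limit in
#' which vapor diffusion concentrates the protein d-fold. For any `K > 0`
#' the ratio is below that limit, so the aqueous concentration an
#' experiment can reach is bounded by the `K = 0` value.
#'
#' @param params A [partition_params()] (or numeric `K`).
#' @param spec A [droplet_spec()].
#' @param system The equilibrated [meso_system()], typically built from
#'   [expected_final_hydration()].
#' @return Dimensionless concentration ratio `>= 0`.
#' @examples
#' spec <- droplet_spec(450, 450, dilution_factor = 1)
#' aqueous_concentration_ratio(50, spec, meso_system(132, 396))
#' @export
aqueous_concentration_ratio <- function(params, spec, system) {
  params <- as_partition_params(params)
  stopifnot(inherits(spec, "droplet_spec"), inherits(system, "meso_system"))
  f <- fraction_incorporated(params, system)
  (1 - f) * spec$protein_volume * spec$dilution_factor / spec$screen_volume
}

#' A partitioning depletion assay
#'
#' One assay in which monoolein-precoated wells are incubated with a known
#' volume of protein solution of known concentration; after 24 h sealed
#' incubation the supernatant is recovered and its protein concentration
#' measured photometrically. Depletion of the supernatant measures uptake
#' into the lipidic phase. `sample_conc`, `applied_volume` and `mo_mass`
#' are recycled to the length of `supernatant_conc`, so replicates may use
#' different applied volumes.
#'
#' Supernatant concentrations above the applied sample concentration are
#' physically impossible under the model; they are flagged, not rejected,
#' since measurement noise can produce them at low depletion.
#'
#' @param sample_conc Applied protein concentration(s), ug/ul.
#' @param applied_volume Applied solution volume(s), nl.
#' @param mo_mass Monoolein mass(es) per well, ug.
#' @param supernatant_conc Measured supernatant concentration(s), ug/ul.
#' @param well Optional well identifiers.
#' @return An object of class `partition_assay` (a data frame, one row per
#'   replicate).
#' @export
partition_assay <- function(sample_conc, applied_volume, mo_mass,
                            supernatant_conc, well = NULL) {
  n <- length(supernatant_conc)
  if (n < 1L) stop_invalid("at least one supernatant measurement is required")
  df <- data.frame(
    well = if (is.null(well)) sprintf("r%02d", seq_len(n)) else as.character(well),
    sample_conc = rep_len(sample_conc, n),
    applied_volume = rep_len(applied_volume, n),
    mo_mass = rep_len(mo_mass, n),
    supernatant_conc = as.numeric(supernatant_conc),
    stringsAsFactors = FALSE)
  if (any(df$sample_conc <= 0) || any(df$applied_volume <= 0) ||
      any(df$mo_mass <= 0) || any(df$supernatant_conc < 0)) {
    stop_invalid("concentrations, volumes and masses must be positive (supernatant >= 0)")
  }
  df$flagged <- df$supernatant_conc > df$sample_conc
  class(df) <- c("partition_assay", class(df))
  df
}

#' Estimate the apparent partitioning constant K from a depletion assay
#'
#' The sealed 24-h assay has no reservoir and no vapor loss, so the total
#' water equals the applied volume (at 1 ug/nl). Per replicate the
#' incorporated fraction is estimated as `f = 1 - C_sup / C_0` and
#' inverted through the partitioning model:
#' \deqn{\hat K = \hat f\, W / ((1 - \hat f)\, M), \quad W = V_{applied}.}
#' A fully depleted supernatant (`C_sup = 0`) leaves `K` unbounded above
#' and is reported as `Inf` with a flag; a supernatant above the sample
#' concentration would imply negative uptake and is reported as `K = 0`
#' with a warning. The assay-level summary is the median over replicates.
#'
#' @param assay A [partition_assay()].
#' @return A list of class `K_estimate`: `K` (median of replicates),
#'   `replicates` (per-replicate data frame with `f_hat`, `K_hat`, `flag`)
#'   and `n`.
#' @examples
#' a <- partition_assay(16, 900, 132, supernatant_conc = 16 * c(.12, .11, .13))
#' estimate_K(a)
#' @export
estimate_K <- function(assay) {
  stopifnot(inherits(assay, "partition_assay"))
  ratio <- assay$supernatant_conc / assay$sample_conc
  f_hat <- 1 - ratio
  W <- assay$applied_volume  # nl * 1 ug/nl
  K_hat <- numeric(nrow(assay))
  flag <- rep(NA_character_, nrow(assay))
  for (i in seq_len(nrow(assay))) {
    if (ratio[i] == 0) {
      K_hat[i] <- Inf
      flag[i] <- "complete depletion: K unbounded above"
    } else if (ratio[i] > 1) {
      K_hat[i] <- 0
      flag[i] <- "supernatant above sample concentration: negative uptake, reported as K = 0"
      warning(sprintf(
        "replicate %s: supernatant concentration exceeds sample concentration; K set to 0",
        assay$well[i]), call. = FALSE)
    } else {
      K_hat[i] <- f_hat[i] * W[i] / ((1 - f_hat[i]) * assay$mo_mass[i])
    }
  }
  reps <- data.frame(well = assay$well, ratio = ratio, f_hat = f_hat,
                     K_hat = K_hat, flag = flag, stringsAsFactors = FALSE)
  structure(list(K = median(K_hat), replicates = reps, n = nrow(reps)),
            class = "K_estimate")
}

#' @export
print.K_estimate <- function(x, ...) {
  cat(sprintf("<K_estimate> apparent K = %.4g (median of %d replicates)\n",
              x$K, x$n))
  invisible(x)
}

#' Percentile bootstrap interval for the apparent K
#'
#' Resamples assay replicates with replacement and recomputes the median
#' apparent K per resample; returns the percentile interval. Deterministic
#' for a given seed.
#'
#' @param assay A [partition_assay()] with at least 3 replicates.
#' @param n_resamples Number of bootstrap resamples (> 0).
#' @param seed Integer seed.
#' @param conf Interval coverage (default 0.95).
#' @return A list with `lower`, `upper`, `K` (point estimate) and
#'   `n_resamples`.
#' @export
bootstrap_K_interval <- function(assay, n_resamples = 2000, seed = 1,
                                 conf = 0.95) {
  stopifnot(inherits(assay, "partition_assay"))
  if (nrow(assay) < 3L) {
    stop_invalid("bootstrap needs at least 3 replicates, got %d", nrow(assay))
  }
  check_number(n_resamples, "n_resamples", lower = 1)
  est <- suppressWarnings(estimate_K(assay))
  k_reps <- est$replicates$K_hat
  stat <- withr::with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      median(sample(k_reps, length(k_reps), replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  list(lower = ci[1], upper = ci[2], K = est$K, n_resamples = n_resamples)
}

#' Read or write a partitioning assay as CSV
#'
#' The on-disk format has columns `well`, `sample_conc_ug_ul`,
#' `applied_volume_nl`, `mo_mass_ug`, `supernatant_conc_ug_ul`.
#'
#' @param path CSV file path.
#' @param assay A [partition_assay()].
#' @return `read_assay_csv()` returns a [partition_assay()];
#'   `write_assay_csv()` returns `path` invisibly.
#' @export
read_assay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "sample_conc_ug_ul", "applied_volume_nl", "mo_mass_ug",
            "supernatant_conc_ug_ul")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_invalid("assay CSV %s is missing column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  partition_assay(sample_conc = df$sample_conc_ug_ul,
                  applied_volume = df$applied_volume_nl,
                  mo_mass = df$mo_mass_ug,
                  supernatant_conc = df$supernatant_conc_ug_ul,
                  well = df$well)
}

#' @rdname read_assay_csv
#' @export
write_assay_csv <- function(assay, path) {
  stopifnot(inherits(assay, "partition_assay"))
  out <- data.frame(well = assay$well,
                    sample_conc_ug_ul = assay$sample_conc,
                    applied_volume_nl = assay$applied_volume,
                    mo_mass_ug = assay$mo_mass,
                    supernatant_conc_ug_ul = assay$supernatant_conc)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
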