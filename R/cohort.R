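#' Configuration of the synthetic-patient simulator
#'
#' The simulator draws patients with known ground truth so that the
#' doubling-time estimator and the downstream timeline pipeline can be
#' validated without clinical data. Defaults describe a realistic serial-
#' imaging scenario: 500 node-negative patients spread uniformly over the
#' size-determined stages, per-stage mean TVDT jittered by a 5-day s.d.,
#' two scans 90 days apart (the second at surgery), and a 5% multiplicative
#' lognormal measurement error on each observed diameter.
#'
#' @param n_patients Number of patients, >= 1.
#' @param stages Stage labels to draw from (size-determined stages only).
#' @param max_diameter Upper cap, mm, for the unbounded T3 interval.
#' @param tvdt_jitter_sd S.d. (days) of Gaussian jitter on the stage TVDT;
#'   jittered values are floored at 20 days.
#' @param noise_sd S.d. of the lognormal multiplicative noise on observed
#'   diameters; 0 for noiseless measurements.
#' @param gap_days Days between consecutive scans, > 0.
#' @param n_measurements Scans per patient, >= 2; the last is at surgery.
#' @param seed Integer seed; fixed seed means an identical cohort.
#' @return An object of class `compas_sim_config`.
#' @export
simulation_config <- function(n_patients = 500,
                              stages = c("T1a", "T1b", "T1c", "T2", "T3"),
                              max_diameter = 75,
                              tvdt_jitter_sd = 5,
                              noise_sd = 0.05,
                              gap_days = 90,
                              n_measurements = 2,
                              seed = 1) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("`n_patients` must be >= 1", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(gap_days) || gap_days <= 0)
    stop("`gap_days` must be > 0", call. = FALSE)
  if (!is.numeric(n_measurements) || n_measurements < 2)
    stop("`n_measurements` must be >= 2", call. = FALSE)
  if (!is.numeric(tvdt_jitter_sd) || tvdt_jitter_sd < 0)
    stop("`tvdt_jitter_sd` must be >= 0", call. = FALSE)
  if (!length(stages))
    stop("`stages` must name at least one stage", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), stages = stages,
                 max_diameter = max_diameter,
                 tvdt_jitter_sd = tvdt_jitter_sd, noise_sd = noise_sd,
                 gap_days = gap_days,
                 n_measurements = as.integer(n_measurements),
                 seed = as.integer(seed)),
            class = "compas_sim_config")
}

#' Simulate a cohort of synthetic patients
#'
#' Each patient gets a stage, a surgery diameter drawn uniformly inside the
#' stage's interval (T3 capped at `max_diameter`), a true TVDT (stage mean
#' plus jitter) and `n_measurements` scans on the noiseless exponential
#' curve ending at surgery, each then perturbed by multiplicative lognormal
#' noise. The true (noiseless) timeline is attached as ground truth.
#'
#' @param cfg A [simulation_config()].
#' @param c Model constants, see [model_constants()].
#' @param table Stage table, see [stage_table()].
#' @return An object of class `compas_cohort`: list of patients, each with
#'   `id`, `stage`, `true_tvdt`, `true_diameter_at_surgery`, `measurements`
#'   (data.frame `offset_days`, `true_diameter_mm`, `observed_diameter_mm`)
#'   and `true_timeline`.
#' @examples
#' coh <- simulate_cohort(simulation_config(n_patients = 5, seed = 7))
#' summarize_recovery(coh)
#' @export
simulate_cohort <- function(cfg = simulation_config(),
                            c = model_constants(),
                            table = stage_table()) {
  stopifnot(inherits(cfg, "compas_sim_config"))
  c <- as_constants(c)
  validate_stage_table(table)
  rows <- match(cfg$stages, table$label)
  if (anyNA(rows) || any(is.na(table$lo[rows])))
    stop("`stages` must name size-determined stages from the table",
         call. = FALSE)
  lo <- table$lo[rows]
  hi <- pmin(table$hi[rows], cfg$max_diameter)
  if (any(hi <= lo))
    stop("degenerate diameter interval after capping at `max_diameter`",
         call. = FALSE)

  set.seed(cfg$seed)
  span <- (cfg$n_measurements - 1) * cfg$gap_days
  patients <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    j <- sample.int(length(rows), 1L)
    stage <- cfg$stages[j]
    d_surg <- stats::runif(1, lo[j], hi[j])
    tvdt <- max(20, table$tvdt_days[rows[j]] +
                  stats::rnorm(1, 0, cfg$tvdt_jitter_sd))
    offs <- seq(0, span, by = cfg$gap_days)
    d_true <- d_surg * 2^(-(span - offs) / (3 * tvdt))
    d_obs <- d_true * exp(stats::rnorm(length(offs), 0, cfg$noise_sd))
    patients[[i]] <- structure(list(
      id = i, stage = stage, true_tvdt = tvdt,
      true_diameter_at_surgery = d_surg,
      measurements = data.frame(offset_days = offs,
                                true_diameter_mm = d_true,
                                observed_diameter_mm = d_obs),
      true_timeline = compute_timeline(
        d_surg, list(stage = stage, tvdt_days = tvdt, k_smts = 1), c)
    ), class = "compas_patient")
  }
  structure(patients, class = "compas_cohort", config = cfg)
}

#' Recover growth parameters of one synthetic patient
#'
#' Estimates TVDT from the first and last observed measurements with the
#' Schwartz estimator, then recomputes the timeline from the last observed
#' diameter using that estimate. Noise can make the later scan smaller than
#' the earlier one; such patients are flagged as unusable (`ok = FALSE`)
#' rather than raising an error, mirroring unusable serial imaging.
#'
#' @param p A patient from [simulate_cohort()].
#' @param c Model constants, see [model_constants()].
#' @return List with `ok`; when `ok`, also `tvdt_days` and `timeline`;
#'   otherwise `reason`.
#' @export
recover_parameters <- function(p, c = model_constants()) {
  stopifnot(inherits(p, "compas_patient"))
  m <- p$measurements
  if (nrow(m) < 2L)
    stop("at least two measurements are required", call. = FALSE)
  d0 <- m$observed_diameter_mm[1L]
  d1 <- m$observed_diameter_mm[nrow(m)]
  dt <- m$offset_days[nrow(m)] - m$offset_days[1L]
  if (d1 <= d0)
    return(list(ok = FALSE, reason = "non-growth between first and last scan"))
  tvdt_hat <- schwartz_doubling_time(measurement_pair(d0, d1, dt))
  tl <- compute_timeline(d1, list(tvdt_days = tvdt_hat, k_smts = 1), c)
  list(ok = TRUE, tvdt_days = tvdt_hat, timeline = tl)
}

#' Estimator-recovery summary over a cohort
#'
#' Runs [recover_parameters()] on every patient and summarises how well the
#' Schwartz estimator recovers the true TVDT and how the error propagates
#' into the predicted survival period. Flagged (non-growing) patients are
#' excluded from the statistics and counted.
#'
#' @param cohort A `compas_cohort`.
#' @param c Model constants, see [model_constants()].
#' @return List: `n`, `n_excluded`, `median_rel_tvdt_error`,
#'   `q90_rel_tvdt_error`, `mean_survival_bias_years`, and the per-patient
#'   `details` data.frame.
#' @export
summarize_recovery <- function(cohort, c = model_constants()) {
  stopifnot(inherits(cohort, "compas_cohort"))
  res <- lapply(cohort, recover_parameters, c = c)
  ok <- vapply(res, `[[`, TRUE, "ok")
  rel_err <- rep(NA_real_, length(res))
  surv_bias <- rep(NA_real_, length(res))
  for (i in which(ok)) {
    rel_err[i] <- abs(res[[i]]$tvdt_days - cohort[[i]]$true_tvdt) /
      cohort[[i]]$true_tvdt
    surv_bias[i] <- res[[i]]$timeline$survival_years -
      cohort[[i]]$true_timeline$survival_years
  }
  details <- data.frame(
    id = vapply(cohort, `[[`, 0L, "id"),
    stage = vapply(cohort, `[[`, "", "stage"),
    ok = ok,
    true_tvdt = vapply(cohort, `[[`, 0, "true_tvdt"),
    est_tvdt = vapply(res, function(r) if (r$ok) r$tvdt_days else NA_real_, 0),
    rel_tvdt_error = rel_err,
    survival_bias_years = surv_bias
  )
  list(n = length(cohort),
       n_excluded = sum(!ok),
       median_rel_tvdt_error = stats::median(rel_err, na.rm = TRUE),
       q90_rel_tvdt_error =
         unname(stats::quantile(rel_err, 0.9, na.rm = TRUE)),
       mean_survival_bias_years = mean(surv_bias, na.rm = TRUE),
       details = details)
}

#' Flatten a cohort to one row per measurement
#'
#' @param x A `compas_cohort`.
#' @param ... Unused.
#' @return A `data.frame` with columns `patient_id`, `stage`, `true_tvdt`,
#'   `true_diameter_at_surgery`, `offset_days`, `true_diameter_mm`,
#'   `observed_diameter_mm`.
#' @export
as.data.frame.compas_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    cbind(data.frame(patient_id = p$id, stage = p$stage,
                     true_tvdt = p$true_tvdt,
                     true_diameter_at_surgery = p$true_diameter_at_surgery),
          p$measurements, row.names = NULL)
  }))
}

#' Write / read a cohort
#'
#' CSV holds the flat one-row-per-measurement schema of
#' [as.data.frame.compas_cohort()]; JSON nests measurements per patient.
#' `read_cohort()` returns the flat measurement table in either case.
#'
#' @param cohort A `compas_cohort`.
#' @param path Output (input) file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   reading.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `data.frame`.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(cohort)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      lapply(cohort, function(p) {
        list(id = p$id, stage = p$stage, true_tvdt = p$true_tvdt,
             true_diameter_at_surgery = p$true_diameter_at_surgery,
             measurements = p$measurements)
      }), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      cbind(data.frame(patient_id = recs$id[i], stage = recs$stage[i],
                       true_tvdt = recs$true_tvdt[i],
                       true_diameter_at_surgery =
                         recs$true_diameter_at_surgery[i]),
            recs$measurements[[i]], row.names = NULL)
    })))
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.compas_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic cohort: %d patients, noise sd %.3g, seed %d\n",
              length(x), cfg$noise_sd, cfg$seed))
  invisible(x)
}
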