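#' Decompose the whole natural history for one patient
#'
#' Core of the model. The primary tumor (PT) grows exponentially from a
#' single founder cell; at its `seeding_doubling`-th volume doubling (1 mm,
#' ~10^6 cells under the defaults) it sheds the first metastatic cell, and
#' the metastasis (MTS) then grows at `tvdt_days / k_smts` per doubling.
#' Death occurs when the shared clock reaches `lethal_total_doublings`
#' (the MTS completes 60 - 20 = 40 doublings, ~103 mm). The whole natural
#' history (WNH) splits into four consecutive periods:
#'
#' * non-visible PT: first cell to the 1 mm PT visibility threshold;
#' * visible PT: visibility to surgery (equals non-visible MTS-I, the occult
#'   MTS growth before surgery);
#' * non-visible MTS-II: surgery until the MTS reaches 9 mm;
#' * visible MTS: 9 mm to the lethal endpoint.
#'
#' Survival (surgery to death) is the sum of the last two. All periods are
#' returned in years (`days_per_year` days each).
#'
#' Degenerate inputs are flagged rather than fatal: a PT below the seeding
#' size yields an MTS-not-yet-seeded timeline with zeroed MTS-at-surgery
#' fields (`mts_seeded = FALSE`), and a PT so large that the MTS would
#' already be clinically manifest reports a zero non-visible MTS-II period
#' with `mts_manifest_at_surgery = TRUE` instead of a negative one.
#'
#' @param d_surgery PT diameter at surgery (resection), mm.
#' @param params Stage parameters from [stage_parameters()], or a list with
#'   `tvdt_days` and optionally `k_smts` (default 1) for a direct TVDT.
#' @param c Model constants, see [model_constants()].
#' @return An object of class `compas_timeline`; see Details for fields.
#' @examples
#' compute_timeline(4.5, stage_parameters("T1a"))
#' @export
compute_timeline <- function(d_surgery, params, c = model_constants()) {
  c <- as_constants(c)
  if (!is.numeric(d_surgery) || length(d_surgery) != 1L ||
      !is.finite(d_surgery))
    stop("`d_surgery` must be a single finite number", call. = FALSE)
  if (d_surgery <= c$founder_diameter)
    stop("`d_surgery` must exceed the founder-cell diameter", call. = FALSE)
  if (is.null(params$tvdt_days))
    stop("`params` must carry `tvdt_days`", call. = FALSE)
  tvdt <- params$tvdt_days
  k <- if (is.null(params$k_smts)) 1 else params$k_smts
  if (tvdt <= 0 || k <= 0)
    stop("`tvdt_days` and `k_smts` must be positive", call. = FALSE)

  n_s    <- doublings_from_diameter(d_surgery, c)
  n_seed <- c$seeding_doubling
  n_mvis <- doublings_from_diameter(c$mts_visible_diameter, c)
  n_tot  <- c$lethal_total_doublings
  if (n_s > n_tot)
    stop("PT of ", d_surgery, " mm implies ", round(n_s, 2),
         " doublings, past the lethal clock of ", n_tot, call. = FALSE)

  tau <- tvdt / k                      # days per MTS doubling
  dpy <- c$days_per_year
  seeded <- n_s >= n_seed
  mts_dbl <- max(0, n_s - n_seed)

  nonvisible_pt   <- n_seed * tvdt / dpy
  visible_pt      <- mts_dbl * tvdt / dpy
  total_pt        <- n_s * tvdt / dpy
  nonvisible_mts1 <- mts_dbl * tau / dpy
  mts2_raw        <- (n_mvis - (n_s - n_seed)) * tau / dpy
  manifest        <- mts2_raw < 0
  nonvisible_mts2 <- max(0, mts2_raw)
  visible_mts     <- ((n_tot - n_seed) - n_mvis) * tau / dpy
  survival        <- (n_tot - n_s) * tau / dpy
  wnh             <- n_tot * tvdt / dpy

  structure(list(
    diameter_at_surgery = d_surgery,
    stage = if (is.null(params$stage)) NA_character_ else params$stage,
    tvdt_days = tvdt,
    k_smts = k,
    pt_doublings_at_surgery = n_s,
    mts_seeded = seeded,
    mts_doublings_at_surgery = mts_dbl,
    mts_diameter_at_surgery =
      if (seeded) diameter_from_doublings(mts_dbl, c) else 0,
    mts_manifest_at_surgery = manifest,
    wnh_years = wnh,
    total_pt_years = total_pt,
    nonvisible_pt_years = nonvisible_pt,
    visible_pt_years = visible_pt,
    nonvisible_mts1_years = nonvisible_mts1,
    nonvisible_mts2_years = nonvisible_mts2,
    visible_mts_years = visible_mts,
    survival_years = survival
  ), class = "compas_timeline")
}

#' Timeline straight from a diameter (stage inferred)
#'
#' Convenience wrapper: classifies the T stage from the diameter, looks up
#' the node-negative stage parameters and computes the timeline.
#'
#' @inheritParams compute_timeline
#' @param table Stage table, see [stage_table()].
#' @return A `compas_timeline`.
#' @examples
#' timeline_for_diameter(15.1)  # stage T1c, survival ~5.4 years
#' @export
timeline_for_diameter <- function(d_surgery, c = model_constants(),
                                  table = stage_table()) {
  stage <- classify_t_stage(d_surgery, table)
  compute_timeline(d_surgery, stage_parameters(stage, "N0", table), c)
}

#' @export
print.compas_timeline <- function(x, ...) {
  cat(sprintf("Natural-history timeline (PT %.4g mm at surgery",
              x$diameter_at_surgery))
  if (!is.na(x$stage)) cat(", stage ", x$stage, sep = "")
  cat(sprintf(", TVDT %.1f d)\n", x$tvdt_days))
  cat(sprintf("  PT doublings at surgery : %.1f\n", x$pt_doublings_at_surgery))
  if (x$mts_seeded) {
    cat(sprintf("  MTS doublings at surgery: %.2f (diameter %.2f mm)\n",
                x$mts_doublings_at_surgery, x$mts_diameter_at_surgery))
  } else {
    cat("  MTS not yet seeded at surgery\n")
  }
  fmt <- function(lab, v) cat(sprintf("  %-24s: %5.1f y\n", lab, v))
  fmt("Whole natural history", x$wnh_years)
  fmt("Total PT period", x$total_pt_years)
  fmt("Non-visible PT", x$nonvisible_pt_years)
  fmt("Visible PT", x$visible_pt_years)
  fmt("Non-visible MTS-I", x$nonvisible_mts1_years)
  fmt("Non-visible MTS-II", x$nonvisible_mts2_years)
  fmt("Visible MTS", x$visible_mts_years)
  fmt("Survival", x$survival_years)
  if (x$mts_manifest_at_surgery)
    cat("  [MTS clinically manifest at surgery]\n")
  invisible(x)
}

#' @export
as.data.frame.compas_timeline <- function(x, ...) {
  data.frame(lapply(unclass(x), function(v) v), stringsAsFactors = FALSE)
}

#' Calendar dates of the timeline landmarks
#'
#' Anchors a computed timeline at the surgery date and places the six
#' landmark events: first PT cell, PT reaching visibility, MTS seeding,
#' surgery, MTS manifestation, lethal endpoint. Offsets are computed in
#' fractional days and rounded to whole calendar days.
#'
#' @param t A `compas_timeline` from [compute_timeline()].
#' @param surgery_date A `Date` (or string coercible to one).
#' @param c Model constants, see [model_constants()].
#' @return An object of class `compas_events`: named `Date` vector with
#'   elements `first_pt_cell`, `pt_visible`, `mts_seeded`, `surgery`,
#'   `mts_visible`, `lethal`.
#' @export
anchor_events <- function(t, surgery_date, c = model_constants()) {
  stopifnot(inherits(t, "compas_timeline"))
  c <- as_constants(c)
  surgery_date <- as.Date(surgery_date)
  dpy <- c$days_per_year
  # PT visibility is a diameter threshold (1 mm), slightly before the
  # seeding doubling (20 doublings = 1.016 mm), so compute it directly.
  n_pvis <- doublings_from_diameter(c$pt_visible_diameter, c)
  pt_visible_off <- -max(0, t$pt_doublings_at_surgery - n_pvis) *
    t$tvdt_days / dpy
  off <- c(
    first_pt_cell = -t$total_pt_years,
    pt_visible    = pt_visible_off,
    mts_seeded    = -t$nonvisible_mts1_years,
    surgery       = 0,
    mts_visible   = t$nonvisible_mts2_years,
    lethal        = t$survival_years
  ) * dpy
  ev <- surgery_date + round(off)
  class(ev) <- c("compas_events", "Date")
  ev
}

#' @export
print.compas_events <- function(x, ...) {
  d <- x
  class(d) <- "Date"
  for (nm in names(d))
    cat(sprintf("  %-14s %s\n", nm, format(d[[nm]])))
  invisible(x)
}

#' Sampled growth curves of PT and MTS on the shared clock
#'
#' Samples both exponential diameter curves from the first PT cell (time 0)
#' to the lethal endpoint. The PT curve stops at surgery (the tumor is
#' resected; `NA` thereafter); the MTS curve is zero before seeding. The
#' final sample always lands exactly on the lethal endpoint, where the MTS
#' diameter is ~103 mm under the defaults.
#'
#' @inheritParams compute_timeline
#' @param step_days Sampling step, days, positive.
#' @return A `data.frame` with columns `t_days`, `pt_diameter_mm`,
#'   `mts_diameter_mm`.
#' @export
growth_curve <- function(d_surgery, params, c = model_constants(),
                         step_days = 30) {
  c <- as_constants(c)
  if (!is.numeric(step_days) || length(step_days) != 1L || step_days <= 0)
    stop("`step_days` must be a single positive number", call. = FALSE)
  t <- compute_timeline(d_surgery, params, c)
  dpy <- c$days_per_year
  wnh_days <- t$wnh_years * dpy
  surgery_days <- t$total_pt_years * dpy
  seed_days <- t$nonvisible_pt_years * dpy  # = seeding_doubling * tvdt
  tau <- t$tvdt_days / t$k_smts
  grid <- unique(c(seq(0, wnh_days, by = step_days), surgery_days, wnh_days))
  grid <- sort(grid)

  pt_n <- grid / t$tvdt_days
  pt <- diameter_from_doublings(pt_n, c)
  pt[grid > surgery_days] <- NA_real_
  mts <- rep(0, length(grid))
  after <- grid >= seed_days
  mts[after] <- diameter_from_doublings((grid[after] - seed_days) / tau, c)
  data.frame(t_days = grid, pt_diameter_mm = pt, mts_diameter_mm = mts)
}
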