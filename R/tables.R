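#' Round half away from zero to a number of decimals
#'
#' Presentation rounding used for the per-stage report tables (base R
#' `round()` rounds half to even, which does not match the printed style).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Default per-stage mean diameters at surgery
#'
#' Mean primary-tumor diameter at resection for each size-determined stage,
#' taken from registry data: 4.5, 8.5, 15.1, 28.5 and 64.6 mm for
#' T1a/T1b/T1c/T2/T3.
#'
#' @return Named numeric vector, mm.
#' @export
stage_mean_diameters <- function() {
  c(T1a = 4.5, T1b = 8.5, T1c = 15.1, T2 = 28.5, T3 = 64.6)
}

timelines_for <- function(diameters, c, table) {
  lapply(diameters, timeline_for_diameter, c = c, table = table)
}

#' Per-stage state-at-surgery report table
#'
#' Recomputes, for each diameter, the PT doubling count at surgery, the
#' stage TVDT and metastasis-rate coefficient, and the doubling count and
#' diameter of the secondary distant metastasis at the surgery date.
#' Values are rounded half-up to the conventional printed precision; the
#' unrounded values are kept in the `"unrounded"` attribute.
#'
#' @param diameters Named or unnamed vector of PT diameters at surgery, mm.
#' @param c Model constants, see [model_constants()].
#' @param table Stage table, see [stage_table()].
#' @return A `data.frame`, quantities in rows and one column per case,
#'   with attribute `unrounded`.
#' @examples
#' natural_history_table()
#' @export
natural_history_table <- function(diameters = stage_mean_diameters(),
                                  c = model_constants(),
                                  table = stage_table()) {
  tls <- timelines_for(diameters, c, table)
  col <- function(f) vapply(tls, f, 0)
  raw <- rbind(
    pt_diameter_at_surgery_mm = col(function(t) t$diameter_at_surgery),
    pt_doublings              = col(function(t) t$pt_doublings_at_surgery),
    tvdt_pt_days              = col(function(t) t$tvdt_days),
    k_smts                    = col(function(t) t$k_smts),
    tvdt_mts_days             = col(function(t) t$tvdt_days / t$k_smts),
    mts_doublings             = col(function(t) t$mts_doublings_at_surgery),
    mts_diameter_mm           = col(function(t) t$mts_diameter_at_surgery)
  )
  digits <- c(1, 1, 1, 2, 1, 2, 2)
  finish_table(raw, digits, tls)
}

#' Per-stage critical-periods report table
#'
#' Recomputes the timeline decomposition for each diameter: whole natural
#' history, total / non-visible / visible PT periods, occult metastasis
#' periods before and after surgery, visible metastasis period and survival,
#' all in years at one decimal (half-up). Unrounded values are kept in the
#' `"unrounded"` attribute.
#'
#' @inheritParams natural_history_table
#' @return A `data.frame` as in [natural_history_table()].
#' @export
critical_periods_table <- function(diameters = stage_mean_diameters(),
                                   c = model_constants(),
                                   table = stage_table()) {
  tls <- timelines_for(diameters, c, table)
  col <- function(f) vapply(tls, f, 0)
  raw <- rbind(
    pt_diameter_at_surgery_mm = col(function(t) t$diameter_at_surgery),
    pt_doublings              = col(function(t) t$pt_doublings_at_surgery),
    tvdt_pt_days              = col(function(t) t$tvdt_days),
    wnh_years                 = col(function(t) t$wnh_years),
    total_pt_years            = col(function(t) t$total_pt_years),
    nonvisible_pt_years       = col(function(t) t$nonvisible_pt_years),
    visible_pt_years          = col(function(t) t$visible_pt_years),
    nonvisible_mts1_years     = col(function(t) t$nonvisible_mts1_years),
    nonvisible_mts2_years     = col(function(t) t$nonvisible_mts2_years),
    visible_mts_years         = col(function(t) t$visible_mts_years),
    survival_years            = col(function(t) t$survival_years)
  )
  digits <- c(1, 1, 1, rep(1, 8))
  finish_table(raw, digits, tls)
}

finish_table <- function(raw, digits, tls) {
  stages <- vapply(tls, function(t) t$stage, "")
  colnames(raw) <- make.unique(stages)
  rounded <- raw
  for (i in seq_len(nrow(raw)))
    rounded[i, ] <- round_half_up(raw[i, ], digits[i])
  out <- as.data.frame(rounded)
  attr(out, "unrounded") <- as.data.frame(raw)
  attr(out, "digits") <- digits
  out
}

#' Reference (printed) values of the per-stage tables
#'
#' The transcribed published per-stage tables, shipped as a plain-text
#' fixture, for cell-by-cell comparison with the recomputed ones.
#'
#' @return Named list of two `data.frame`s: `state` (state at surgery) and
#'   `periods` (critical periods).
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.csv", package = "compas",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_one <- function(which) {
    sub <- df[df$table == which, ]
    out <- sub[, c("T1a", "T1b", "T1c", "T2", "T3")]
    rownames(out) <- sub$row
    out
  }
  list(state = split_one("state"), periods = split_one("periods"))
}

#' Cell-by-cell comparison of recomputed vs reference tables
#'
#' Recomputes both per-stage tables at the default diameters and reports
#' each cell's deviation from the transcribed reference. A cell agrees when
#' it matches within one unit in the last printed digit (a handful of
#' published cells were derived from pre-rounded intermediates).
#'
#' @param c Model constants, see [model_constants()].
#' @param table Stage table, see [stage_table()].
#' @return A `data.frame` with columns `table`, `row`, `stage`, `computed`,
#'   `reference`, `deviation`, `within_last_digit`.
#' @export
compare_tables <- function(c = model_constants(), table = stage_table()) {
  ref <- reference_tables()
  comp <- list(state = natural_history_table(c = c, table = table),
               periods = critical_periods_table(c = c, table = table))
  out <- list()
  for (which in names(ref)) {
    r <- ref[[which]]
    cm <- comp[[which]][rownames(r), , drop = FALSE]
    dg <- attr(comp[[which]], "digits")[match(rownames(r),
                                              rownames(comp[[which]]))]
    for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
      dev <- cm[i, j] - r[i, j]
      out[[length(out) + 1L]] <- data.frame(
        table = which, row = rownames(r)[i], stage = colnames(r)[j],
        computed = cm[i, j], reference = r[i, j], deviation = dev,
        within_last_digit = abs(dev) <= 10^(-dg[i]) + 1e-9)
    }
  }
  do.call(rbind, out)
}
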