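#' Model constants for the shared doubling clock
#'
#' The natural-history model places the primary tumor (PT) and its secondary
#' distant metastases (MTS) on one clock measured in volume doublings of a
#' single founder cell. `model_constants()` bundles the fixed anchors of that
#' clock. The defaults are the model's canonical values: a 10 um founder cell,
#' metastatic seeding at the PT's 20th doubling (diameter 1 mm, ~10^6 cells),
#' death when the clock reaches 60 doublings, a 1 mm detectability threshold
#' for the PT and 9 mm for a distant metastasis.
#'
#' @param founder_diameter Diameter of the first tumor cell, mm.
#' @param seeding_doubling PT doubling count at which the first metastatic
#'   cell is shed; also the PT visibility doubling under the defaults.
#' @param lethal_total_doublings Doubling count on the shared clock at death.
#' @param pt_visible_diameter Detectability threshold for the PT, mm.
#' @param mts_visible_diameter Threshold at which a distant metastasis counts
#'   as clinically manifest, mm.
#' @param days_per_year Calendar conversion used for all year-valued periods.
#'
#' @return An object of class `compas_constants` (a named list).
#' @examples
#' c0 <- model_constants()
#' diameter_from_doublings(c0$seeding_doubling, c0)  # 1 mm at seeding
#' @export
model_constants <- function(founder_diameter = 0.01,
                            seeding_doubling = 20,
                            lethal_total_doublings = 60,
                            pt_visible_diameter = 1,
                            mts_visible_diameter = 9,
                            days_per_year = 365.25) {
  vals <- list(
    founder_diameter = founder_diameter,
    seeding_doubling = seeding_doubling,
    lethal_total_doublings = lethal_total_doublings,
    pt_visible_diameter = pt_visible_diameter,
    mts_visible_diameter = mts_visible_diameter,
    days_per_year = days_per_year
  )
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single strictly positive number", call. = FALSE)
  }
  if (seeding_doubling >= lethal_total_doublings)
    stop("`seeding_doubling` must be smaller than `lethal_total_doublings`",
         call. = FALSE)
  if (!(pt_visible_diameter < mts_visible_diameter &&
        mts_visible_diameter < 103))
    stop("visibility thresholds must satisfy pt < mts < 103 mm", call. = FALSE)
  structure(vals, class = "compas_constants")
}

#' @export
print.compas_constants <- function(x, ...) {
  cat("Natural-history model constants\n")
  cat(sprintf("  founder cell diameter : %g mm\n", x$founder_diameter))
  cat(sprintf("  MTS seeded at doubling: %g (PT %g mm)\n", x$seeding_doubling,
              diameter_from_doublings(x$seeding_doubling, x)))
  cat(sprintf("  lethal clock doubling : %g\n", x$lethal_total_doublings))
  cat(sprintf("  visibility thresholds : PT %g mm, MTS %g mm\n",
              x$pt_visible_diameter, x$mts_visible_diameter))
  cat(sprintf("  days per year         : %g\n", x$days_per_year))
  invisible(x)
}

as_constants <- function(c) {
  if (inherits(c, "compas_constants")) return(c)
  stop("`c` must be created with model_constants()", call. = FALSE)
}
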