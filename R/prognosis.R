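#' Life-forecast class from the first-metastasis appearance period
#'
#' The forecast bands key on how long after surgery the first distant
#' metastasis becomes clinically manifest (the non-visible MTS-II period of
#' the timeline): more than five years is favourable, three to five years
#' (inclusive) moderately favourable, under three years unfavourable.
#'
#' @param first_mts_period Years from surgery to first MTS manifestation;
#'   nonnegative. Typically `timeline$nonvisible_mts2_years`.
#' @return An object of class `compas_prognosis`: list with `label` (one of
#'   `"favourable"`, `"moderately_favourable"`, `"unfavourable"`) and
#'   `basis_years`.
#' @examples
#' classify_prognosis(timeline_for_diameter(4.5)$nonvisible_mts2_years)
#' @export
classify_prognosis <- function(first_mts_period) {
  check_period(first_mts_period)
  label <- if (first_mts_period > 5) "favourable"
           else if (first_mts_period >= 3) "moderately_favourable"
           else "unfavourable"
  structure(list(label = label, basis_years = first_mts_period),
            class = "compas_prognosis")
}

#' Metastasis-risk group from the first-metastasis appearance period
#'
#' Groups patients by when distant metastases are expected to appear:
#' within 5 years of surgery is high risk, 5-10 years medium, 10 years or
#' later low. The sub-year interval (0, 1) is folded into high risk, the
#' conservative choice.
#'
#' @inheritParams classify_prognosis
#' @return An object of class `compas_risk`: list with `label` (`"high"`,
#'   `"medium"` or `"low"`) and `window_years` (the group's interval).
#' @export
risk_group <- function(first_mts_period) {
  check_period(first_mts_period)
  if (first_mts_period < 5)
    out <- list(label = "high", window_years = c(0, 5))
  else if (first_mts_period < 10)
    out <- list(label = "medium", window_years = c(5, 10))
  else
    out <- list(label = "low", window_years = c(10, Inf))
  out$basis_years <- first_mts_period
  structure(out, class = "compas_risk")
}

check_period <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("period must be a single finite number", call. = FALSE)
  if (x < 0)
    stop("period must be nonnegative", call. = FALSE)
  invisible(x)
}

#' @export
print.compas_prognosis <- function(x, ...) {
  cat(sprintf("Prognosis: %s (first MTS at %.1f y after surgery)\n",
              gsub("_", " ", x$label), x$basis_years))
  invisible(x)
}

#' @export
print.compas_risk <- function(x, ...) {
  cat(sprintf("MTS risk: %s (window %g-%g y; first MTS at %.1f y)\n",
              x$label, x$window_years[1], x$window_years[2], x$basis_years))
  invisible(x)
}
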