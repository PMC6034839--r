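#' Convert a tumor diameter to a volume-doubling count
#'
#' Under exponential volume growth from a single spherical founder cell, a
#' tumor of diameter `d` has completed `3 * log2(d / d_founder)` volume
#' doublings (the diameter gains a factor 2^(1/3) per volume doubling).
#'
#' @param d Tumor diameter, mm. Vectorised.
#' @param c Model constants, see [model_constants()].
#' @return Volume-doubling count(s), dimensionless.
#' @examples
#' doublings_from_diameter(4.5)  # ~26.4 doublings for a 4.5 mm tumor
#' @export
doublings_from_diameter <- function(d, c = model_constants()) {
  c <- as_constants(c)
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("`d` must be finite numeric", call. = FALSE)
  if (any(d <= 0))
    stop("diameter must be positive", call. = FALSE)
  if (any(d < c$founder_diameter))
    stop("diameter below the founder-cell diameter (",
         c$founder_diameter, " mm)", call. = FALSE)
  3 * log2(d / c$founder_diameter)
}

#' Convert a volume-doubling count to a tumor diameter
#'
#' Inverse of [doublings_from_diameter()]: `d_founder * 2^(n/3)`. After 20
#' doublings a 10 um founder cell reaches 1 mm; after 40 doublings, 103 mm
#' (about 10^12 cells), the lethal burden.
#'
#' @param n Volume-doubling count(s), nonnegative.
#' @inheritParams doublings_from_diameter
#' @return Diameter(s), mm.
#' @export
diameter_from_doublings <- function(n, c = model_constants()) {
  c <- as_constants(c)
  if (!is.numeric(n) || any(!is.finite(n)))
    stop("`n` must be finite numeric", call. = FALSE)
  if (any(n < 0))
    stop("doubling count must be nonnegative", call. = FALSE)
  c$founder_diameter * 2^(n / 3)
}

#' Cell count after a number of volume doublings
#'
#' One cell at doubling 0; `2^n` cells after `n` doublings (2^20 ~ 10^6 at
#' 1 mm, 2^40 ~ 10^12 at the lethal size).
#'
#' @param n Volume-doubling count(s), nonnegative.
#' @return Cell count(s), real-valued.
#' @export
cell_count_from_doublings <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)))
    stop("`n` must be finite numeric", call. = FALSE)
  if (any(n < 0))
    stop("doubling count must be nonnegative", call. = FALSE)
  2^n
}

#' Spherical tumor volume from diameter
#'
#' @param d Diameter(s), mm, positive.
#' @return Volume(s), mm^3 (`pi * d^3 / 6`).
#' @export
volume_from_diameter <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)))
    stop("`d` must be finite numeric", call. = FALSE)
  if (any(d <= 0))
    stop("diameter must be positive", call. = FALSE)
  pi * d^3 / 6
}

#' Two dated diameter measurements of one tumor
#'
#' Container for the serial-imaging input of the Schwartz doubling-time
#' estimator: an earlier diameter `d0`, a later diameter `d1`, and the days
#' elapsed between them.
#'
#' @param d0 Diameter at the first measurement, mm.
#' @param d1 Diameter at the second (pre-surgery) measurement, mm; must
#'   exceed `d0`.
#' @param delta_days Days between the measurements, positive.
#' @return An object of class `compas_measurement_pair`.
#' @export
measurement_pair <- function(d0, d1, delta_days) {
  for (v in list(d0 = d0, d1 = d1, delta_days = delta_days))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("measurement fields must be single finite numbers", call. = FALSE)
  if (d0 <= 0)
    stop("first diameter must be positive", call. = FALSE)
  if (d1 <= d0)
    stop("no growth between measurements: the doubling-time estimator ",
         "requires d1 > d0", call. = FALSE)
  if (delta_days <= 0)
    stop("measurements out of chronological order: delta_days must be ",
         "positive", call. = FALSE)
  structure(list(d0 = d0, d1 = d1, delta_days = delta_days),
            class = "compas_measurement_pair")
}

#' Schwartz estimator of the tumor volume doubling time
#'
#' Classical two-measurement estimator: with volumes `V0`, `V1` a time
#' `delta_days` apart, `TVDT = delta_days * log(2) / (log(V1) - log(V0))`.
#' The value is independent of the logarithm base, and because volume scales
#' with the cube of diameter it equals `delta_days / (3 * log2(d1 / d0))`.
#'
#' @param m A [measurement_pair()], or a diameter `d0` if `d1` and
#'   `delta_days` are supplied directly.
#' @param d1,delta_days Optional; supply together with a numeric first
#'   argument instead of a `measurement_pair`.
#' @return Estimated TVDT, days.
#' @examples
#' schwartz_doubling_time(measurement_pair(5, 10, 210))  # 70 days
#' @export
schwartz_doubling_time <- function(m, d1 = NULL, delta_days = NULL) {
  if (!inherits(m, "compas_measurement_pair"))
    m <- measurement_pair(m, d1, delta_days)
  v0 <- volume_from_diameter(m$d0)
  v1 <- volume_from_diameter(m$d1)
  m$delta_days * log(2) / (log(v1) - log(v0))
}
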