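# Independent oracles used to freeze expected values.

# Invert diameter_from_doublings by bisection, without using the closed-form
# log expression under test.
bisect_doublings <- function(d, c = model_constants(), lo = 0, hi = 200,
                             tol = 1e-10) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (diameter_from_doublings(mid, c) < d) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force Schwartz evaluation straight from the volume-log definition,
# in an arbitrary log base.
schwartz_brute <- function(d0, d1, delta_days, base = 10) {
  v0 <- pi * d0^3 / 6
  v1 <- pi * d1^3 / 6
  delta_days * log(2, base) / (log(v1, base) - log(v0, base))
}

default_diameters <- c(T1a = 4.5, T1b = 8.5, T1c = 15.1, T2 = 28.5, T3 = 64.6)
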