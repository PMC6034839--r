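---
title: "A shared doubling clock for breast-cancer primary tumors and distant metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shared doubling clock for breast-cancer primary tumors and distant metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compas)
```

## The model

`compas` implements a deterministic exponential model of the whole natural
history of node-negative breast cancer. A primary tumor (PT) grows from a
single founder cell of diameter $d_0 = 10\ \mu m$ by repeated volume
doublings; because volume scales with the cube of diameter, a tumor of
diameter $d$ has completed

$$ n(d) = 3 \log_2 (d / d_0) $$

volume doublings and contains $2^{n}$ cells. The clock's anchors: 20
doublings is $\approx 1$ mm and $\sim 10^6$ cells, 30 doublings 10 mm and
$\sim 10^9$, 40 doublings 103 mm and $\sim 10^{12}$ — the lethal burden.

The model's structural assumptions are:

1. PT growth is exponential in volume, characterised by a constant tumor
   volume doubling time (TVDT, days);
2. the first distant metastatic cell is shed when the PT completes its
   20th doubling (1 mm, $\sim 10^6$ cells);
3. the metastasis (MTS) grows at the same rate as the PT (the rate ratio
   `k_smts` is kept as an explicit parameter, fixed at 1.00 for
   node-negative disease, so nodal extensions can change it without an API
   change);
4. death occurs when the shared clock reaches 60 doublings, i.e. the MTS
   has completed $60 - 20 = 40$ doublings ($\approx 103$ mm); the PT is
   resected at surgery and contributes nothing thereafter.

Under these assumptions the whole natural history (WNH) of one patient
decomposes exactly into four consecutive periods — non-visible PT (first
cell to the 1 mm detectability threshold), visible PT (detectability to
surgery, identically the occult MTS growth before surgery), non-visible
MTS after surgery (until the MTS reaches the 9 mm clinical-manifestation
threshold), and visible MTS (9 mm to death). Survival is the sum of the
last two. With $n_s$ the PT doublings at surgery, TVDT $\tau$ and all
periods in years ($365.25$ d),

$$ \text{survival} = (60 - n_s)\,\tau, \qquad
   \text{WNH} = 60\,\tau . $$

Everything the package reports — the per-stage tables, calendar events,
growth curves, prognosis bands — is bookkeeping on these identities.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| founder diameter | 0.01 | mm | a single 10 um cell; configurable for sensitivity analysis |
| seeding doubling | 20 | doublings | first MTS cell at PT $\approx$ 1 mm / $10^6$ cells |
| lethal clock | 60 | doublings | MTS completes 40 doublings ($\approx 103$ mm) at death |
| PT visibility | 1 | mm | forced by the non-visible-PT period equalling $20\tau$ in the reference decomposition |
| MTS visibility | 9 | mm | the only threshold that reproduces the published post-surgery periods (narrative text elsewhere says "1–5" or "5–10" mm; 9 mm is what the numbers use) |
| stage TVDT | 70/70/70/65/60/47 | days | per-stage means for T1a–T3; T4 is the midpoint of a stated 46–48 d range |
| `k_smts` | 1.00 | — | MTS/PT rate ratio for N0 |

Only node-negative (N0) disease is in scope; asking for `N+` parameters is
a deliberate error, because growth with regional lymph-node involvement is
outside the model's validity.

### TVDT from serial imaging

Two dated diameter measurements identify the TVDT through the classical
two-point (Schwartz) estimator
$\mathrm{TVDT} = \Delta t \,\log 2 / (\log V_1 - \log V_0)
= \Delta t / (3 \log_2 (d_1/d_0))$,
which is independent of the logarithm base and of whether volumes or
diameters are measured. It is undefined for non-growing pairs
($d_1 \le d_0$); the package refuses them at construction.

## Numerical choices

* All computation is done in full double precision on diameters (doubling
  arithmetic as $3\log_2$ ratios); volumes appear only in the estimator's
  presentation and reports. Rounding happens only at presentation, half
  away from zero, one decimal for years and doubling counts, two for
  sub-millimetre MTS diameters.
* A few cells of the published reference tables were evidently derived
  from pre-rounded intermediates (visible PT at T1c prints 2.3 where
  direct computation gives 2.2387 → 2.2; the T2 non-visible PT and
  survival cells are similar). The comparison utility (`compare_tables()`)
  therefore accepts ±1 unit in the last printed digit, and the tests
  assert the recomputed value for those cells.
* 20 doublings of a 10 um cell is 1.0159 mm, not exactly 1 mm, so "PT
  visible at 1 mm" and "MTS seeded at the 20th doubling" are two slightly
  different instants. Period bookkeeping follows the doubling clock (the
  non-visible PT period is $20\tau$, as the reference decomposition
  requires); calendar-event anchoring places the PT-visibility event from
  the 1 mm diameter threshold so that the six landmark events are strictly
  ordered.
* Degenerate inputs are flagged, not fatal: a PT below the seeding size
  returns an `mts_seeded = FALSE` timeline with zeroed MTS fields, and a
  PT so large that the MTS would already be manifest reports a zero
  (flagged) non-visible MTS-II period rather than a negative one. The
  four-period sum identity holds exactly (to $10^{-9}$ y) for every seeded
  timeline, and the tests enforce it over a 1–75 mm sweep.
* Stage intervals are half-open on the right exactly as defined
  ("1 < d ≤ 5"), so a 5.0 mm tumor is T1a; tumors of 1 mm or less are
  unstageable by size, and T4 is never inferred from size.
* Prognosis bands: "more than five years" is strict (exactly 5.0 y is
  moderately favourable) and "from three" is inclusive (exactly 3.0 y is
  moderately favourable). The risk windows leave (0, 1) y formally
  unassigned; the package folds it into high risk, the conservative
  choice.
* The first-MTS "appearance period" driving prognosis and risk is the
  post-surgery non-visible MTS period (surgery to 9 mm manifestation) —
  the only post-surgery appearance interval the model computes.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws patients with known ground truth: a stage
(uniform over T1a–T3, with the unbounded T3 interval capped at 75 mm, the
range over which the model was exercised), a surgery diameter uniform in
the stage interval, a true TVDT equal to the stage mean plus Gaussian
jitter (s.d. 5 d, floored at 20 d), and two scans 90 days apart on the
noiseless exponential curve ending at surgery. Measurement error is
multiplicative lognormal on diameter (default s.d. 5%): error scales with
size and diameters stay positive. Noise, gap and cohort size follow the
package's estimator-recovery scenario; the jitter s.d. and the T3 cap are
this package's own choices, made once.

The generator emulates exponential growth with imaging noise and nothing
else: no cell loss, no treatment effect, no inter-patient growth-law
heterogeneity, no detection bias in who gets imaged. A green recovery test
therefore establishes that the estimator and pipeline are correct under
the model's own assumptions — not that real tumors grow exponentially.
Patients whose noisy second scan is not larger than the first are flagged
and excluded from recovery statistics (with the exclusion count reported),
mirroring clinically unusable serial imaging.

## Known limitations

* Validity is claimed only for T1a–T3, N0, M0 at surgery; nodal disease
  and primary metastatic disease are refused, not extrapolated.
* Growth-law alternatives (Gompertz, logistic, von Bertalanffy) are out of
  scope; the model is deliberately a constant-TVDT exponential.
* The published external-survival validation (correlations against
  independently fitted 10/15-year survival functions) cannot be recomputed
  here because those functions' parameters are not available; the
  package's property-based test suite substitutes structural checks
  (period-sum conservation, monotone survival, exact estimator recovery)
  for it.
* The piecewise "linear phase" refinement sometimes written alongside the
  model is not used by any of the numbers the model produces and is not
  implemented; the doubling-clock identities generate every reported
  value.

## A worked check

```{r}
tl <- timeline_for_diameter(15.1)   # T1c mean diameter
tl
classify_prognosis(tl$nonvisible_mts2_years)
risk_group(tl$nonvisible_mts2_years)
```

The full per-stage tables are regenerated by `natural_history_table()` and
`critical_periods_table()`, and `compare_tables()` reports the cellwise
deviation from the transcribed reference values shipped in
`inst/extdata/reference_tables.csv`.
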