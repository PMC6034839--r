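# compas

A deterministic exponential-growth model of the whole natural history of
node-negative breast cancer, for biostatisticians and modellers who need a
transparent, reproducible baseline for tumor-kinetics reasoning: how long a
primary tumor (PT) grew before it became detectable, when it seeded its
first distant metastasis (MTS), and how much time remains after surgery
before that metastasis becomes clinically manifest and, eventually, lethal.

## The model in one paragraph

A PT grows from a single 10 um founder cell by volume doublings at a
constant tumor volume doubling time (TVDT); a tumor of diameter $d$ has
completed $n(d) = 3\log_2(d/0.01\,\mathrm{mm})$ doublings and holds $2^n$
cells (20 doublings ≈ 1 mm ≈ 10^6 cells; 40 doublings ≈ 103 mm ≈ 10^12
cells, the lethal burden). The first metastatic cell is shed at the PT's
20th doubling and grows at the same rate; death occurs when the shared
clock reaches 60 doublings. The whole natural history then splits exactly
into non-visible PT, visible PT (= occult MTS before surgery), non-visible
MTS after surgery (to the 9 mm manifestation threshold) and visible MTS;
survival after surgery at PT doubling count $n_s$ is
$(60 - n_s)\cdot\mathrm{TVDT}$. From two dated scans the TVDT is estimated
by the classical two-point formula
$\mathrm{TVDT} = \Delta t\,\log 2 / (\log V_1 - \log V_0)$.

## Worked example

```r
library(compas)
tl <- timeline_for_diameter(15.1)   # 15.1 mm tumor at surgery
tl
```

```
Natural-history timeline (PT 15.1 mm at surgery, stage T1c, TVDT 70.0 d)
  PT doublings at surgery : 31.7
  MTS doublings at surgery: 11.68 (diameter 0.15 mm)
  Whole natural history   :  11.5 y
  Total PT period         :   6.1 y
  Non-visible PT          :   3.8 y
  Visible PT              :   2.2 y
  Non-visible MTS-I       :   2.2 y
  Non-visible MTS-II      :   3.4 y
  Visible MTS             :   2.0 y
  Survival                :   5.4 y
```

Reading: a 15.1 mm tumor (T stage T1c, per-stage mean TVDT 70 days) has
undergone 31.7 volume doublings over 6.1 years; its first distant
metastasis, seeded 2.2 years before surgery, is a sub-detectable 0.15 mm
at the surgery date, will become clinically manifest (9 mm) 3.4 years
after surgery, and reaches the lethal size 5.4 years after surgery.

```r
classify_prognosis(tl$nonvisible_mts2_years)
#> Prognosis: moderately favourable (first MTS at 3.4 y after surgery)
risk_group(tl$nonvisible_mts2_years)
#> MTS risk: high (window 0-5 y; first MTS at 3.4 y)

schwartz_doubling_time(measurement_pair(11, 14.2, 160))  # two scans, 160 d
#> [1] 144.7751
```

Other entry points: `natural_history_table()` / `critical_periods_table()`
regenerate the per-stage reference tables (and `compare_tables()` diffs
them against the transcribed published values), `anchor_events()` places
the six landmark dates around a surgery date, `growth_curve()` samples
both diameter curves, and `simulate_cohort()` / `summarize_recovery()`
build synthetic patients with noisy serial scans and measure how well the
two-point estimator recovers the truth.

A command line is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "compas", package = "compas"))')" \
    timeline --diameter 15.1
```

with subcommands `timeline`, `tvdt`, `tables`, `simulate`, `curve`
(`--help` for options; exit status 0 on success, 2 on usage/domain
errors).

## Scope

Node-negative (N0), non-metastatic disease with size-determined T stages
T1a–T3 only; node-positive parameters are refused by design. See
`vignettes/compas-model.Rmd` for the model's assumptions, parameter
rationale, numerical choices and limitations.
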