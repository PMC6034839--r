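Package: compas
Title: Deterministic Exponential Natural-History Model of Breast Cancer
    Primary Tumors and Distant Metastases
Version: 1.0.0
Authors@R: person("compas", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Implements CoMPaS, a deterministic exponential-growth model of
    the whole natural history of breast cancer, in which the primary tumor
    and its secondary distant metastases share a single 60-doubling clock.
    Provides conversions between tumor diameter, volume, cell count and
    volume-doubling count from a single 10 micrometre founder cell; the
    Schwartz two-measurement estimator of tumor volume doubling time (TVDT);
    TNM size-based T staging with per-stage TVDT parameters; decomposition
    of the full timeline into non-visible and visible growth periods of the
    primary tumor and metastases with survival prediction; prognosis and
    metastasis-risk classification; a synthetic-cohort simulator with noisy
    serial measurements for estimator-recovery studies; and a command-line
    interface that regenerates the per-stage reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
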