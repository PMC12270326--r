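Package: manodrift
Title: Thermal-Drift Compensation and Chicago-Style Analysis of Esophageal
    Pressure Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing high-resolution esophageal manometry
    pressure topographies recorded with solid-state catheters that suffer
    thermal baseline drift. Provides a synthetic generator for 10-swallow
    supine studies with motility-disorder archetypes and per-sensor drift,
    baseline-offset estimation anchored at configurable post-removal time
    points with linear-in-time drift subtraction, quality-control screening,
    Chicago-style swallow metrics (integrated relaxation pressure, distal
    contractile integral, distal latency, contraction strength and pattern),
    a diagnostic decision tree over those metrics, and nonparametric cohort
    comparison across compensation conditions with compact letter displays
    and diagnosis flip tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nortest,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
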