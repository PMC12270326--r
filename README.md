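# manodrift

Thermal-drift compensation and Chicago-style analysis of esophageal
pressure topography.

## The problem

Solid-state high-resolution manometry (HRM) catheters — 36 pressure
sensors at 1-cm spacing, rendered as a space–time Clouse plot — warm
from room to body temperature during a study, and their baselines drift
with them. The vendor correction, *thermal compensation* (TC), measures
each sensor's residual offset at an operator-chosen anchor instant after
the catheter leaves the body (the end of the "waterfall image") and
subtracts the inferred drift from the recording. But the residual
offset itself evolves over the seconds after withdrawal, so anchoring
the measurement at the wrong instant — or skipping compensation
entirely — subtracts the wrong drift, shifts the integrated relaxation
pressure (IRP) across its 15-mmHg diagnostic threshold, and can turn a
normal study into an esophagogastric-junction outflow obstruction
(EGJ-OO) diagnosis or vice versa.

`manodrift` is for investigators who want to study that mechanism
quantitatively. It provides:

* a synthetic generator of 10-swallow supine studies with
  motility-disorder archetypes and per-sensor thermal drift
  (`simulate_study()`, `simulate_cohort()`) — patient recordings of
  this kind are not publicly deposited, so ground truth is built in;
* baseline-offset estimation at configurable post-removal anchors
  (0, 1, 5, 10 s) and linear-in-time drift subtraction
  (`estimate_offsets()`, `apply_compensation()`, `compensate()`);
* quality-control screening (`qc_screen()`): post-removal tail ≥ 10 s,
  duration ≤ 15 min, no residual sensor pressure, no catheter fold;
* the Chicago-style metric set (`analyze_study()`): UESP, LESP, the
  eSleeve IRP (mean of the lowest 4 s within a 10-s deglutitive
  window, gastric-referenced), the distal contractile integral
  (DCI, pressure excess above a gastric-referenced 20-mmHg floor),
  the distal latency (DL) via a two-segment fit of 30-mmHg contour
  arrivals whose breakpoint is the contractile deceleration point,
  contraction strength/pattern labels and panesophageal
  pressurization;
* the hierarchical diagnostic decision tree over those metrics
  (`classify_diagnosis()`: achalasia types 1–3, EGJ-OO, absent
  contractility, achalasia-cannot-rule-out, spasm, hypercontractile
  esophagus, ineffective motility, fragmented peristalsis, normal);
* cohort comparison across the five compensation conditions
  (`compare_conditions()`, `run_pipeline()`): Kruskal–Wallis and
  Mann–Whitney tests with a compact letter display, per-diagnosis
  chi-square with adjusted residuals, and the diagnosis-by-IRP-category
  flip table (`build_flip_table()`).

## Worked example

Simulate a borderline-normal study (expected median IRP just below
15 mmHg) with the default heterogeneous drift, then analyze it under
all five compensation conditions:

```r
library(manodrift)

st <- simulate_study("nem_borderline", drift_model(), seed = 4)
st
#> <pressure_study 'nem_s0004'>: 36 sensors x 15600 samples (312.0 s at 50 Hz)
#>   catheter exit at 300.00 s; 10 swallows; spacing 1 cm
#>   simulator ground truth: NEM

for (cond in c("nontc", "ftc", "tc1", "tc5", "tc10")) {
  sm <- analyze_study(st, cond)
  dg <- classify_diagnosis(sm)
  cat(sprintf("%-6s median IRP %5.2f mmHg  DCI %6.0f  -> %s\n",
              cond, sm$median_irp, sm$median_dci, dg$label))
}
#> nontc  median IRP 16.12 mmHg  DCI   1343  -> EGJ_OO
#> ftc    median IRP 14.80 mmHg  DCI   1296  -> NEM
#> tc1    median IRP 14.72 mmHg  DCI   1294  -> NEM
#> tc5    median IRP 14.78 mmHg  DCI   1296  -> NEM
#> tc10   median IRP 14.92 mmHg  DCI   1301  -> NEM
```

The study is normal by construction, and every compensated analysis
agrees — but omitting compensation leaves ~1.3 mmHg of net
sleeve-versus-gastric drift in the recording, pushes the median IRP over
the 15-mmHg threshold, and misdiagnoses the study as outflow
obstruction. That is the phenomenon the package exists to quantify:
drift matters only through *between-sensor heterogeneity* (a spatially
uniform offset cancels out of every gastric-referenced metric, a
property the test suite checks to 10⁻⁶), and it matters most for
studies near the IRP threshold.

Cohort-scale runs go through one call:

```r
spec <- cohort_spec(c(nem = 10, egjoo = 10, iem = 10, t2a = 10), seed = 1)
res <- run_pipeline(spec, "report/")
```

which writes the manifest, QC report, metric summary (median (IQR) per
condition), diagnosis counts with chi-square p-values, the flip
cross-tab and the test statistics, plus the resolved configuration for
provenance.

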