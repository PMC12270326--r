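---
title: "Thermal drift, compensation anchoring, and Chicago-style diagnosis: the manodrift methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{manodrift methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manodrift)
```

## The problem

Solid-state high-resolution manometry (HRM) catheters carry 36
circumferential pressure sensors at 1-cm spacing. As the sensors warm
from room to body temperature their baselines drift, so a recording that
starts calibrated against atmospheric pressure ends with a nonzero
per-sensor offset — visible as residual pressure after the catheter has
left the body. The vendor correction ("thermal compensation", TC)
measures those residual offsets at an operator-chosen anchor instant
after withdrawal — conventionally the end of the "waterfall image",
where anatomical pressure collapses to atmospheric on every sensor — and
subtracts the inferred drift from the whole recording. Because the
post-removal offset itself evolves over the seconds after withdrawal,
anchoring the measurement at different instants (0, 1, 5 or 10 s after
the waterfall ends) subtracts different offsets, shifts the derived
metrics, and can flip the final motility diagnosis. `manodrift`
implements the full chain needed to study that effect: a synthetic study
generator, the compensation model, quality control, the Chicago-style
metric set, the diagnostic decision tree, and cohort comparison across
the five anchoring conditions (none, formal/0 s, 1 s, 5 s, 10 s).

Patient recordings of this kind are not publicly deposited, so the
package ships a generator rather than data: every empirical statement
the test suite makes is about simulated cohorts whose ground truth is
known by construction.

## Coordinate and unit conventions

* Pressures are mmHg relative to atmospheric at calibration time; drift
  therefore appears as a nonzero post-removal baseline.
* Sensor 1 is the most proximal (pharyngeal) sensor; indices increase
  distally — the top-down reading order of a Clouse plot.
* Time is seconds from recording start. Sample *j* (1-based) covers the
  half-open interval [(j−1)/fs, j/fs); every analysis window is
  half-open [t0, t0+w), which makes all window sample counts exact
  integers at the default 50 Hz.
* The default sampling rate of 50 Hz is a package choice (vendor
  hardware rates vary and are rarely reported); it resolves the 4-s IRP
  span to 200 samples. All functions take fs from the study object, and
  the metric suite checks stability under refinement to 100 Hz.

## The drift model

Each sensor *i* draws an amplitude \(D_i = \max(0, \mu + \sigma Z)\)
(defaults \(\mu = 6\), \(\sigma = 3\) mmHg). In the body the accrued
drift is a saturating warm-up
\(d_i(t) = D_i\,(1 - e^{-t/\tau})\) with \(\tau = 120\) s (a linear
accrual variant exists for closed-form checks). After withdrawal at
\(t_{exit}\) the residual offset is
\(D_i\,(1 - e^{-t_{exit}/\tau})\, g(\Delta t)\), where the post-exit
shape

\[ g(\Delta t) = 1 + 0.1\,\frac{\Delta t}{2.5}\,
   e^{1 - \Delta t / 2.5} - 0.009\,\Delta t \]

rises to a mild peak near 2.5 s and decays below 1 by 10 s
(\(g(0) = 1\), \(g(1) \approx 1.06\), \(g(5) \approx 1.03\),
\(g(10) \approx 0.93\)). The published literature establishes that
offsets measured at different post-removal instants differ, but not the
kinetics; this shape is a declared model assumption, chosen so that the
1-s and 5-s anchors over-subtract and the 10-s anchor under-subtracts
relative to the formal anchor, and it is fully configurable
(`drift_model()`).

Spatial heterogeneity (\(\sigma > 0\)) is the load-bearing choice. A
spatially uniform offset — however large — cancels out of every metric
the package computes, because all of them are referenced to the mean
intragastric pressure recorded by sensors distal to the LES. Only
between-sensor differences (sleeve sensors drifting differently from
gastric sensors) can move the integrated relaxation pressure across its
15-mmHg threshold. The test suite asserts both halves of this statement:
uniform drift changes no metric by more than 10⁻⁶ even without any
compensation, and heterogeneous drift produces IRP-category flips in
both directions.

Measurement noise is Gaussian with sd 1 mmHg during the in-body phase
(physiological plus electronic artifact) and sd 0.2 mmHg after
withdrawal, when the catheter hangs in air and only electronic noise
remains; a 1.5-mmHg respiratory sinusoid (0.25 Hz) rides on the
sphincter bands. All three are disableable, which the closed-form tests
use.

## The synthetic protocol and archetypes

A simulated study follows the standard supine protocol: a quiet
accommodation baseline, ten 5-mL water swallows at 25-s intervals,
withdrawal 45 s after the last onset (t_exit = 300 s by default), and a
12-s post-removal tail. The anatomy is a fixed geometry — UES band at
sensors 3–5, esophageal body 6–29, LES band 30–32, gastric sensors
33–36 — plus per-swallow events: a brief UES relaxation, a deglutitive
EGJ relaxation to an archetype-specific gastric-referenced residual
(the main driver of the measured IRP), and a peristaltic contraction
modeled as a Gaussian ridge (temporal sd 0.8 s) whose center travels
distally at 3.5 cm/s and decelerates to 1.2 cm/s at the contractile
deceleration point, 3 cm above the LES band. Premature waves travel at
8 cm/s; fragmented waves suppress the ridge to 25% over a 7-cm
mid-body stretch; panesophageal pressurization is a brief (0.3 s)
33-mmHg gastric-referenced isobaric column over the whole body span.

Each archetype (`archetype()`) is a parameter set calibrated once, at
design time, so that the simulated study satisfies its own diagnostic
criteria in expectation: contraction amplitudes of ~70 mmHg yield DCI
near 1300 mmHg·s·cm (normal), ~40 mmHg ~250 (weak), ~260 mmHg
~9800 (hypercontractile); EGJ relaxation residuals place the median IRP
near 5 (normal), 21 (outflow obstruction) or 26 mmHg (achalasia). The
measured IRP sits ~1.9 mmHg below the programmed residual because the
eSleeve takes an instantaneous minimum over three sensors and the IRP
averages the lowest 4 s — both order statistics that select the noise
floor; the presets account for this. Two deliberately unstable variants,
`nem_borderline` (expected IRP ≈ 14) and `egjoo_borderline` (≈ 16),
bracket the 15-mmHg threshold; they exist to study drift-induced
diagnosis flips and are excluded from the archetype-fidelity contract
(≥ 18 of 20 drift-free studies reproducing their own label) that the
eleven standard presets satisfy.

What the generator does *not* emulate: pathological EGJ morphologies,
hiatal hernia double high-pressure zones, swallow-to-swallow landmark
migration, catheter folding pressure patterns (folding enters only as an
annotation), upright or rapid-swallow protocols, and any drift source
other than warming. Passing tests therefore demonstrate the pipeline's
arithmetic and the drift mechanism, not clinical performance on real
tracings.

## Compensation model

`estimate_offsets()` averages each sensor over the half-open 0.5-s
window starting at the anchor (t_exit + 0, 1, 5 or 10 s); a window mean
rather than a point sample suppresses noise, at the cost of a small bias
where the post-exit shape has slope (about 2.5% of the offset at the
0-s anchor, the largest case). `apply_compensation()` subtracts
\(o_i\, r(t)\) with \(r(t) = \min(t, t_{exit})/t_{exit}\): zero
correction at recording start, the full measured offset at exit, and a
constant correction afterwards so that exit detection is stable on
corrected studies. The vendor's in-recording interpolation is
proprietary; linear accrual is the simplest model consistent with a
monotone warming process and is stated as such wherever it matters. On
simulated studies with genuinely linear in-body drift and a flat
post-exit shape, formal compensation recovers drift-free metrics to
numerical precision, which is the closed-form anchor for this design.

`detect_waterfall_end()` operationalizes "end of the waterfall image"
as the earliest post-swallow instant at which the spatial range of
temporally smoothed pressures stays below 15 mmHg for 0.5 s. With the
default drift distribution the post-exit spatial range is ~11 mmHg, so
detection succeeds and agrees with the annotated exit within half a
second; residual pressure held on sensors (a planted quality-control
scenario) correctly defeats it.

## Metrics

All metrics are referenced to the mean of three gastric sensors located
immediately distal to the detected LES band; this includes the 20-mmHg
DCI floor and the 30-mmHg DL contour, making uniform-offset
cancellation provable rather than approximate.

* **IRP** — eSleeve minimum across the LES band, gastric-referenced;
  the mean of the lowest 4 s worth of samples (noncontiguous, the
  standard eSleeve convention) within the 10-s deglutitive window. The
  efficient implementation (partial sort) is tested against a full-sort
  oracle at 10⁻⁹.
* **DCI** — excess above the gastric-referenced 20-mmHg floor summed
  over the body span and a 15-s post-onset window, times sample
  duration and sensor spacing. A rectangular 30 mmHg × 5 cm × 4 s ridge
  gives exactly (30−20)·5·4 = 200 mmHg·s·cm.
* **DL / CDP** — per-sensor front arrival is the first 30-mmHg contour
  crossing; a continuous two-segment line is least-squares fitted over
  every admissible interior breakpoint (ties broken toward the earliest
  breakpoint, which makes the fit deterministic), the best breakpoint
  is the CDP, and DL is the observed arrival there minus onset. DL is
  undefined for failed swallows and excluded from medians.
* **Strength/pattern** — failed < 100, weak < 450,
  hypercontractile > 8000 mmHg·s·cm; premature DL < 4.5 s and
  fragmented break > 5 cm both require DCI > 450. Weak swallows still
  carry a pattern label, so intact and weak percentages can overlap.
  Study-level values are medians over defined swallows and percentages
  out of the ten wet swallows.

Thresholds not fixed by the defining literature (failed 100, weak 450,
premature 4.5 s, break 5 cm, pressurization 30 mmHg) follow the Chicago
conventions and live in `analysis_params()`, all overridable. Whether
per-study DCI should be a median or a mean over swallows is genuinely
open; the median was chosen to match the IRP convention.

## The decision tree

`classify_diagnosis()` evaluates, with elevated median IRP (> 15 mmHg,
strictly — 15.0 is normal everywhere): type 2 achalasia (100% failed
with ≥ 20% pressurization), type 1 (100% failed), type 3 (no intact
peristalsis, ≥ 20% premature vigorous contractions), else EGJ outflow
obstruction. With normal IRP: achalasia-cannot-rule-out (100% failed,
IRP in the borderline interval (10, 15], pressurization evidence) or
absent contractility (100% failed); then spasm (≥ 20% premature),
hypercontractile esophagus (≥ 2 swallows above 8000), ineffective
motility (> 50% ineffective), fragmented peristalsis (> 50%
fragmented); spasm and ineffective motility firing together emit the
composite DES_IEM, the only composite allowed. Precedence follows the
listing order of the defining criteria; "no normal peristalsis" is
operationalized as 0% intact, "borderline" as (10, 15] and
"pressurization evidence" as ≥ 20% of swallows, all configurable. The
rule trace records every predicate evaluated. Whether hypercontractile
esophagus should outrank ineffective motility when both fire is
unspecified in the source criteria; the listing order (spasm, then
hypercontractile, then ineffective) was adopted. An independent
flat-lookup re-implementation agrees on 10,000 random profiles in the
test suite.

## Cohort statistics

`compare_conditions()` re-analyzes every study under each condition and
mirrors the conventional reporting chain: a two-test normality gate
(one-sample Kolmogorov–Smirnov against the fitted normal plus its
Lilliefors correction; a sample is summarized as mean (sd) only when
both p > 0.05, otherwise median (IQR)), Kruskal–Wallis omnibus tests per
metric, pairwise Mann–Whitney U contrasts with a compact letter display
(letters k, l, m attached to significant pairs only after a significant
omnibus test), and per-diagnosis chi-square tests with adjusted
standardized residuals flagged at |r| > 1.96. The five conditions are
compared as independent groups even though they are the same studies
re-analyzed — this mirrors the conventional (unpaired) presentation; a
paired design would be more powerful and is noted as future work. No
multiple-testing correction is applied, again matching convention.

`build_flip_table()` stratifies the cohort by the reference condition's
IRP category and counts diagnoses per condition within each stratum,
collapsed to NEM / IEM / EGJ-OO / Achalasia / Other. Because EGJ-OO and
the achalasia types require elevated IRP while every other label arises
on the normal-IRP branch, off-stratum diagnoses are diagnosis-implied
category flips; `implied_flips()` extracts them, and they are lower
bounds on the true metric flips. The packaged
`inst/extdata/flip_table_counts.csv` is a verbatim transcription of a
published 124-study cross-tabulation used for fixture arithmetic; it is
transcribed as printed, including its known internal inconsistencies
with the companion diagnosis table, which the package does not attempt
to reconcile.

## Problem sizes and numerical choices

The shipped checks use cohorts the package can analyze in seconds to a
few minutes on one core: 40-study mixed cohorts for the drift-nullability
invariants, 20 seeds × 4 anchors × 36 sensors for offset recovery
(observed worst error ≈ 0.35 mmHg against a 0.5-mmHg contract), a
136-study low-rate (10 Hz) cohort with 12 planted violations for the
screening flow, and an 80-study borderline cohort for the flip
phenomenon. That last size is a power calculation: with the default
drift the per-study probability of an upward IRP-category flip is
≈ 0.09 (downward ≈ 0.25), so 80 borderline studies leave under 0.05%
probability of observing no upward flip — the check is about the
phenomenon, not one lucky seed. Determinism is guaranteed by deriving
every per-study seed from one master seed and advancing the RNG stream
by a fixed number of draws regardless of parameter values, so cohorts
differing only in drift share their anatomy and noise realization.

## Limitations

The generator's fidelity claims end at its own ground truth: archetypes
are caricatures built to satisfy classification criteria, not fitted to
patient data, and the post-exit drift kinetics are an assumption with
the right qualitative signature rather than a measured curve. Landmark
detection assumes two clean sphincter bands and fails (by design,
loudly) on degenerate topographies. Real-world effects outside the drift
mechanism — catheter migration, hernia, vigorous artifact — are out of
scope throughout.
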