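---
title: "Models, parameters and design choices in panometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in panometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panometry)
```

This vignette is the package's account of its science: what the
classification rules are and how they are realised algorithmically, what
the synthetic generators emulate (and deliberately do not), which
parameters matter and why their defaults were chosen, and where the design
was genuinely open.

## The classification model

FLIP panometry evaluates two independent axes of one exam and combines
them through a total decision table.

**Contractile response (CR).** The v2.0 pattern rules operate on a handful
of per-study features, applied with a fixed precedence in
`classify_cr_v2()`:

1. *spastic* if a sustained occluding contraction or a sustained LES
   contraction is present — spastic features dominate every other
   criterion (the normal pattern explicitly excludes them);
2. *normal* if more than one distinct antegrade contraction of at least
   6 cm axial length with an associated pressure rise above 10 mmHg;
3. otherwise, with contractility present, *diminished* when the 60-mL
   pressure is at or below 40 mmHg and *disordered* when above — the
   pressure split is the major v2.0 revision, motivated by spasm being
   rare in low-pressure impaired contractility;
4. *absent* when no esophageal-body contractile activity exists.

Boundary semantics are fixed and tested: pressure exactly 40 mmHg is
diminished ("at or below"); exactly two qualifying contractions is normal
("more than one"). The v1.0 rules (`classify_cr_v1()`) are identical
except that diminished and disordered collapse into one
impaired/disordered pattern; spastic features carry the v1.0 name
spastic-reactive. This makes the coherence property exact: merging the
v2.0 split must reproduce v1.0 on any input, which the suite verifies over
10,000 random metric draws.

**EGJ opening.** `classify_egj_opening()` uses the 60-mL EGJ
distensibility index (EGJ-DI, mm²/mmHg) and the maximum EGJ diameter over
the 60- and 70-mL steps: normal requires EGJ-DI ≥ 2.0 *and* diameter
≥ 16 mm; reduced requires EGJ-DI < 2.0 *and* diameter < 12 mm; everything
else is inconclusive. These numeric cut-offs come from the consensus
literature rather than from a single study; they are shipped as explicit
`flip_params()` defaults and every decision-table cell records whether it
is paper-anchored or a consensus default.

**Motility class.** `classify_motility()` is a pure lookup in a
`decision_table()`. The v2.0 table has 15 cells; the cells for
inconclusive opening are not printed anywhere as a table, so they are
reconstructed from the scheme's figures and tagged `consensus-default`,
overridable per cell. Whether spastic CR with inconclusive opening should
be possible spasm or spastic obstruction is genuinely undocumented; the
default maps it to possible spasm (obstruction labels are reserved for
reduced opening) and `decision_table(overrides = ...)` changes it in one
line. The whole v1.0 table is likewise a documented reconstruction.

## The contraction-event detector

Raters classify CR patterns visually; `detect_contraction_events()` is an
algorithmic stand-in. Within the analysed period (fill ≥ 50 mL), a sample
is contracting when its diameter falls strictly below the *stricter* of
50% of a per-channel rolling-median baseline and a 9-mm absolute floor.
The relative criterion adapts to baseline diameter differences across
channels and fill volumes (and keeps a chronically narrow EGJ from being
read as a contraction); the absolute floor stops wide lumens from needing
implausibly deep dips. Events are maximal 8-connected spatiotemporal
regions of contracting samples; regions closer than 2 s *and* 2 channels
are merged, because the scheme counts *distinct* contractions and the
criteria do not define distinctness — 2 s/2 channels is our stated
operationalisation. Direction comes from the slope of the band centre
against time (antegrade above +0.5 cm/s, retrograde below −0.5 cm/s,
otherwise mixed); the pressure rise is measured against the median bag
pressure over the 5 s before onset. "Sustained" (≥ 10 s) and "occluding"
(minimum diameter ≤ 2 mm) are not quantified in the published criteria;
the defaults are declared choices, all configurable.

The baseline window (25 s rolling median) must exceed twice the longest
sustained occlusion so the occlusion itself cannot drag the baseline
down; with the default 12-s spastic band the occluded samples are always
a minority of any window.

A naive fixpoint label-propagation oracle, independent of the BFS
labelling used in production, verifies identical component partitions on
random grids in the test suite.

## EGJ metrics

`compute_egj_metrics()` takes the *final 10 s* of the 60-mL step as the
EGJ-DI analysis window. The criteria specify the fill volume but not the
window within the step; end-of-step is when the pressure has equilibrated
after filling, and the simulator correspondingly keeps that window free
of contraction events. Medians (not means) summarise the narrowest-EGJ
cross-sectional area and the bag pressure, for robustness to transients.
Cross-sectional area assumes a circular lumen, CSA = π(d/2)². Studies
missing the 60- or 70-mL step raise a protocol-incomplete error, mirroring
the clinical exclusion of technically limited exams.

## What the simulator emulates

`simulate_topography()` reproduces the protocol's skeleton: four fill
steps (40/50/60/70 mL) each held 40 s (within the 30–60 s protocol bound)
at 10 Hz, 16 channels with the EGJ at channels 13–15 and an intragastric
sensor at channel 16. Esophageal-body baseline diameters widen with
distension (12/14/16/18 mm per step); the EGJ trace is constructed so the
60-mL diameter reproduces the requested EGJ-DI exactly at the requested
pressure, and the 70-mL diameter equals the requested maximum.

Contractions are Gaussian-in-space diameter reductions with raised-cosine
onset/offset whose centre travels at the requested velocity; the spatial
width is calibrated against the default detection threshold so the channel
span driven below threshold equals the requested axial extent exactly — a
travelling narrow band whose *traversed* span is the extent, as peristalsis
is measured. A synchronous raised-cosine bag-pressure bump supplies the
contraction-associated pressure rise. All bands are scheduled in the 50-
and 60-mL steps, leaving the EGJ-DI window clean.

Phenotype defaults (chosen once, as typical presentations): normal — three
antegrade 8-cm bands at 3 cm/s, 60-mL pressure 35 mmHg; diminished — two
antegrade 4-cm bands (too short to qualify), 30 mmHg; disordered — two
retrograde 7-cm bands, 55 mmHg; absent — none; spastic — one stationary
12-s occluding band reaching 1 mm (or, as a variant, a sustained EGJ-level
contraction), 50 mmHg. EGJ-opening defaults: normal EGJ-DI 4.0 / maximum
18 mm; inconclusive 1.5 / 14 mm; reduced 1.0 / 10 mm — each comfortably
inside its class so that 0.5-mm diameter noise (a realistic planimetry
jitter) does not flip the classification. Contradictory requests (an
absent CR with contractions; a diminished CR with 60-mL pressure above
40 mmHg; an EGJ-DI/pressure pair implying a 60-mL diameter above the
requested maximum) are rejected at specification time.

What the simulator does *not* emulate: impedance-planimetry physics,
device-specific artifacts, respiratory and cardiac motion, bag migration,
repetitive retrograde contraction trains, or any correlation between
metrics and demographics. Passing round-trip tests therefore demonstrate
the internal consistency of generator, detector and classifier under the
stated noise model — not detector performance on device recordings.

## HRM adjudication

Diagnoses enter as Chicago Classification v4.0 labels; the package does
not classify raw pressure topography. `adjudicate_diagnosis()` applies the
published resolution rules: achalasia of any subtype is a conclusive
outflow disorder regardless of TBE; EGJOO (and, optionally, borderline
absent contractility — the criteria do not say how it resolves, so it is
modelled identically to EGJOO and must be opted in via `pending_labels`)
is resolved by the timed barium esophagram; everything else is conclusive
with normal outflow. The TBE rules use only the 1- and 5-min column
heights and the 12.5-mm tablet outcome; the 2-min image is carried in the
data model but unused, matching the printed criteria. The inconclusive
clause "no tablet administration or tablet passage" is grammatically
ambiguous; the default parses it as (not administered OR passed), with the
alternative parse selectable via `tbe_clause = "passage_only"`.

## The calibrated cohort generator

`calibrate_joint_from_counts()` normalises the packaged 805-patient
contingency table into a joint distribution over FLIP class × HRM
category; `sample_cohort()` draws i.i.d. patients from it and
`attach_metrics()` gives each one a metric row that re-classifies to its
drawn FLIP class under the default thresholds — uniform draws within
per-pattern ranges kept clear of the decision boundaries, because the
criteria fix thresholds, not distributions. Conclusiveness is likewise
reproduced by construction: drawn conclusive-EGJOO patients receive an
abnormal TBE, inconclusive-EGJOO patients a missing one. Demographics
(age 55 ± 17, 62% female, 75% dysphagia) are optional decoration sampled
from the published marginals and never feed classification.

Two printed denominators in the source disagree with its own contingency
table (75 vs 76 conclusive spastic-obstruction patients; 200 vs 199
possible obstruction). The fixture stores the table verbatim; all derived
proportions come from the table and reproduce every printed percentage
either way.

## Statistics and rounding

Cross-tabulations are exact counts with canonical label ordering; every
filter conserves totals. Percentages are rounded half away from zero
(92.7 → 93, 98.5 → 99), matching printed clinical reports; raw fractions
are always retained alongside. Predictive values treat
\{achalasia I/II/III, conclusive EGJOO\} as the positive condition.
`group_comparison_tests()` dispatches the uncorrected χ² test for
categorical variables and t/ANOVA or Mann-Whitney/Kruskal-Wallis for
continuous ones, two-tailed, with no multiplicity correction — the
analysis it mirrors applies none. Confidence intervals for predictive
values are deliberately out of the headline report.

## Numerical choices and problem sizes

Determinism: one integer seed drives a named local RNG stream per study
or cohort (`withr::with_seed`), so identical specifications are
bit-identical and the caller's RNG state is never touched. Noise is
floored at 0.3 mm to keep diameters positive; the floor only engages at
occluded lumens, which sit far below every threshold anyway.

The test suite exercises the simulator round trip over all fifteen
CR × EGJ-opening pairs with 20 seeds each, noise-free and at 0.5-mm noise
(100% and ≥ 95% recovery required); cohort calibration uses 100 seeds of
20,000 patients for the goodness-of-fit property and a single 50,000
draw for the 3-standard-error cell check. These sizes give comfortable
statistical resolution for the assertions made while keeping the default
suite around two minutes on one core.

## Known limitations

* The detector is validated against the package's own generative model;
  real planimetry recordings carry artifact classes it has never seen.
* The v1.0 decision table and the inconclusive-opening cells of the v2.0
  table are reconstructions, clearly provenance-tagged but not verbatim
  criteria.
* Esophageal-body distensibility plateaus, repetitive-retrograde
  sub-phenotyping, and swallow-level HRM metrics (DCI, distal latency)
  are out of scope; HRM enters as labels only.
* `proportion_within()` returns an undefined marker for empty classes
  (e.g. obstruction with normal CR, observed in no patient) rather than
  extrapolating.
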